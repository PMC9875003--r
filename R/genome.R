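#' Construct a genome (genetic map)
#'
#' A genome is an ordered set of chromosomes with lengths in Morgans and
#' strictly increasing marker positions in `[0, length]`.  Marker positions
#' are held in Morgans internally; centimorgan or physical coordinates are
#' converted at I/O time only.
#'
#' @param chrom data.frame with columns `name`, `length_m` (Morgans).
#' @param markers data.frame with columns `id`, `chrom`, `pos_m` (Morgans),
#'   ordered by chromosome then position.
#' @return an object of class `bo_genome` with fields `chrom`, `markers`,
#'   `n_snp`, and integer index vectors `chr_start`/`chr_end` delimiting
#'   each chromosome's markers in genome order.
#' @export
bo_genome <- function(chrom, markers) {
  stopifnot(is.data.frame(chrom), is.data.frame(markers))
  stopifnot(all(c("name", "length_m") %in% names(chrom)))
  stopifnot(all(c("id", "chrom", "pos_m") %in% names(markers)))
  if (any(chrom$length_m <= 0)) stop("chromosome lengths must be > 0")
  chrom$name <- as.character(chrom$name)
  markers$chrom <- as.character(markers$chrom)
  markers$id <- as.character(markers$id)
  if (!all(markers$chrom %in% chrom$name)) {
    stop("marker assigned to unknown chromosome: ",
         paste(unique(setdiff(markers$chrom, chrom$name)), collapse = ", "))
  }
  # enforce genome order: chromosomes as listed, positions increasing
  ord <- order(match(markers$chrom, chrom$name), markers$pos_m)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  chr_start <- integer(nrow(chrom))
  chr_end <- integer(nrow(chrom))
  for (l in seq_len(nrow(chrom))) {
    idx <- which(markers$chrom == chrom$name[l])
    chr_start[l] <- if (length(idx)) min(idx) else 0L
    chr_end[l] <- if (length(idx)) max(idx) else -1L
    if (length(idx)) {
      p <- markers$pos_m[idx]
      if (any(diff(p) <= 0)) {
        stop("marker positions not strictly increasing on chromosome ",
             chrom$name[l])
      }
      if (any(p < 0) || any(p > chrom$length_m[l])) {
        stop("marker position outside [0, length] on chromosome ",
             chrom$name[l])
      }
    }
  }
  structure(
    list(chrom = chrom, markers = markers, n_snp = nrow(markers),
         chr_start = chr_start, chr_end = chr_end),
    class = "bo_genome"
  )
}

#' @export
print.bo_genome <- function(x, ...) {
  cat("<bo_genome> ", nrow(x$chrom), " chromosomes, ", x$n_snp,
      " markers, total map length ", sum(x$chrom$length_m), " M\n", sep = "")
  invisible(x)
}

#' Number of markers per chromosome
#' @param genome a [bo_genome()].
#' @return integer vector, one entry per chromosome.
#' @export
n_snp_per_chrom <- function(genome) {
  pmax(genome$chr_end - genome$chr_start + 1L, 0L)
}

#' Construct a population
#'
#' Individuals are diploid; the two haplotypes are stored as binary
#' matrices `H1`, `H2` (individuals x markers, genome marker order).  The
#' allele dose at a marker is `H1 + H2` and lies in 0/1/2.
#'
#' @param genome a [bo_genome()].
#' @param H1,H2 binary integer matrices, one row per individual.
#' @param ids character vector of unique individual ids.
#' @param generation integer vector (recycled) of generation indices, 0 for
#'   founders.
#' @param mother,father parent ids (`NA` for founders); identical ids mean
#'   selfing.
#' @return an object of class `bo_pop`.
#' @export
bo_pop <- function(genome, H1, H2, ids,
                   generation = 0L, mother = NA_character_,
                   father = NA_character_) {
  stopifnot(inherits(genome, "bo_genome"))
  H1 <- as.matrix(H1); H2 <- as.matrix(H2)
  storage.mode(H1) <- "integer"; storage.mode(H2) <- "integer"
  n <- nrow(H1)
  if (n < 1L) stop("a population needs at least one individual")
  stopifnot(nrow(H2) == n, ncol(H1) == genome$n_snp, ncol(H2) == genome$n_snp)
  if (!all(H1 %in% c(0L, 1L)) || !all(H2 %in% c(0L, 1L))) {
    stop("haplotype entries must be binary")
  }
  ids <- as.character(ids)
  stopifnot(length(ids) == n, !anyDuplicated(ids))
  rownames(H1) <- ids; rownames(H2) <- ids
  colnames(H1) <- genome$markers$id; colnames(H2) <- genome$markers$id
  structure(
    list(genome = genome, ids = ids, H1 = H1, H2 = H2,
         generation = rep_len(as.integer(generation), n),
         mother = rep_len(as.character(mother), n),
         father = rep_len(as.character(father), n)),
    class = "bo_pop"
  )
}

#' @export
print.bo_pop <- function(x, ...) {
  cat("<bo_pop> ", length(x$ids), " individuals, generation(s) ",
      paste(unique(x$generation), collapse = ","), ", ",
      x$genome$n_snp, " markers\n", sep = "")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a [bo_pop()].
#' @export
n_ind <- function(pop) length(pop$ids)

#' Allele-dose matrix of a population
#'
#' @param pop a [bo_pop()].
#' @return integer matrix (individuals x markers) with entries in 0/1/2,
#'   columns in genome marker order, rows named by individual id.
#' @export
dosage_matrix <- function(pop) {
  pop$H1 + pop$H2
}

#' Simulate a homozygous founder panel
#'
#' Emulates a fully homozygous diploid panel (e.g. an inbred soybean
#' collection): `n_chr` chromosomes of `chr_length` Morgans each, markers
#' placed uniformly at random then sorted, and for each marker an alt-allele
#' frequency `f` drawn from `maf_law`; every founder is independently
#' homozygous alt (dose 2) with probability `f`, else homozygous ref
#' (dose 0).  Markers are generated independent of each other (no founder
#' LD).
#'
#' @param n_ind number of founders (>= 2).
#' @param n_chr number of chromosomes (>= 1); default 20.
#' @param n_snp total marker count (>= n_chr); default 3000.  Markers are
#'   split as evenly as possible over chromosomes.
#' @param maf_law alt-allele frequency law: either a length-2 numeric
#'   `c(min, max)` for a uniform draw on that interval (default
#'   `c(0.05, 0.5)`), or a single number in (0, 1) used for every marker.
#' @param chr_length chromosome length in Morgans (default 1).
#' @param seed integer seed; the output is a deterministic function of it.
#' @return `list(genome = bo_genome, pop = bo_pop)`.
#' @export
simulate_founders <- function(n_ind, n_chr = 20L, n_snp = 3000L,
                              maf_law = c(0.05, 0.5), chr_length = 1,
                              seed = 1L) {
  stopifnot(n_ind >= 2, n_chr >= 1, n_snp >= n_chr, chr_length > 0)
  if (length(maf_law) == 1L) {
    if (maf_law <= 0 || maf_law >= 1) stop("fixed allele frequency must be in (0, 1)")
  } else if (length(maf_law) == 2L) {
    if (maf_law[1] <= 0 || maf_law[2] > 0.5 || maf_law[1] >= maf_law[2]) {
      stop("maf_law bounds must satisfy 0 < min < max <= 0.5")
    }
  } else stop("maf_law must be length 1 or 2")
  set.seed(seed)
  per_chr <- split_evenly(n_snp, n_chr)
  chrom <- data.frame(name = paste0("chr", seq_len(n_chr)),
                      length_m = rep(chr_length, n_chr))
  pos <- unlist(lapply(per_chr, function(k) sort(runif(k, 0, chr_length))))
  markers <- data.frame(
    id = paste0("m", seq_len(n_snp)),
    chrom = rep(chrom$name, per_chr),
    pos_m = pos
  )
  genome <- bo_genome(chrom, markers)
  f <- if (length(maf_law) == 2L) runif(n_snp, maf_law[1], maf_law[2]) else
    rep(maf_law, n_snp)
  alt <- matrix(runif(n_ind * n_snp) < rep(f, each = n_ind),
                nrow = n_ind, ncol = n_snp)
  H <- matrix(as.integer(alt), nrow = n_ind)
  pop <- bo_pop(genome, H, H, ids = sprintf("F%03d", seq_len(n_ind)),
                generation = 0L)
  list(genome = genome, pop = pop)
}

#' Randomly subset the markers of a population
#'
#' Samples `n_keep` markers uniformly without replacement, preserving
#' genome order and positions, and returns a new population on the reduced
#' genome.
#'
#' @param pop a [bo_pop()].
#' @param n_keep number of markers to keep (1 <= n_keep <= n_snp).
#' @param seed integer seed for the marker draw.
#' @return a [bo_pop()] on the subset genome.
#' @export
subset_markers <- function(pop, n_keep, seed = 1L) {
  g <- pop$genome
  if (n_keep <= 0) stop("n_keep must be positive")
  if (n_keep > g$n_snp) stop("n_keep exceeds the marker count")
  set.seed(seed)
  keep <- sort(sample.int(g$n_snp, n_keep))
  markers <- g$markers[keep, , drop = FALSE]
  genome <- bo_genome(g$chrom, markers)
  bo_pop(genome, pop$H1[, keep, drop = FALSE], pop$H2[, keep, drop = FALSE],
         ids = pop$ids, generation = pop$generation,
         mother = pop$mother, father = pop$father)
}

#' Read founders from a dosage CSV or VCF plus a genetic map
#'
#' The map gives each marker's chromosome and physical position plus each
#' chromosome's physical and Morgan length; Morgan positions are obtained
#' by linear rescaling `pos_m = phys_pos / phys_len * morgan_len`.
#' Founders are expected fully homozygous; in `strict` mode a dose-1
#' (heterozygous) call is an error, in lenient mode it is rounded to a
#' random homozygote and counted in a message.
#'
#' @param genotype_file path to either a CSV dosage matrix (first column
#'   individual id, remaining columns markers, values 0/2 — 1 only in
#'   lenient mode) or a VCF (`.vcf`) of biallelic SNPs with GT fields
#'   (needs the VariantAnnotation package).
#' @param map_spec list with `markers` (data.frame `marker`, `chrom`,
#'   `phys_pos`) and `chromosomes` (data.frame `chrom`, `phys_len`,
#'   `morgan_len`), or a list of two file paths `markers`/`chromosomes`
#'   pointing at CSVs with those columns.
#' @param strict reject heterozygous founders (default TRUE).
#' @return `list(genome = bo_genome, pop = bo_pop)`.
#' @export
load_founders <- function(genotype_file, map_spec, strict = TRUE) {
  map <- normalise_map_spec(map_spec)
  if (grepl("\\.vcf$", genotype_file, ignore.case = TRUE)) {
    dos <- read_vcf_dosages(genotype_file)
  } else {
    raw <- read.csv(genotype_file, check.names = FALSE)
    dos <- as.matrix(raw[, -1, drop = FALSE])
    rownames(dos) <- as.character(raw[[1]])
  }
  markers <- map$markers
  missing <- setdiff(colnames(dos), markers$marker)
  if (length(missing)) {
    stop("markers absent from the map: ", paste(head(missing, 5), collapse = ", "))
  }
  markers <- markers[match(colnames(dos), markers$marker), , drop = FALSE]
  chrs <- map$chromosomes
  unknown <- setdiff(markers$chrom, chrs$chrom)
  if (length(unknown)) stop("unknown chromosome in map: ", paste(unknown, collapse = ", "))
  j <- match(markers$chrom, chrs$chrom)
  pos_m <- markers$phys_pos / chrs$phys_len[j] * chrs$morgan_len[j]
  if (any(markers$phys_pos < 0) || any(markers$phys_pos > chrs$phys_len[j])) {
    stop("physical position outside [0, phys_len]")
  }
  mk <- data.frame(id = markers$marker, chrom = markers$chrom, pos_m = pos_m)
  # break exact position ties by the smallest representable bump, in map order
  ord <- order(match(mk$chrom, chrs$chrom), mk$pos_m)
  mk <- mk[ord, , drop = FALSE]
  for (cn in unique(mk$chrom)) {
    idx <- which(mk$chrom == cn)
    p <- mk$pos_m[idx]
    dup <- which(diff(p) <= 0)
    if (length(dup)) {
      message(length(dup), " tied map position(s) on ", cn,
              " perturbed by the minimal increment")
      for (d in dup) p[d + 1L] <- p[d] + .Machine$double.eps * max(1, abs(p[d]))
      mk$pos_m[idx] <- p
    }
  }
  genome <- bo_genome(
    data.frame(name = chrs$chrom, length_m = chrs$morgan_len),
    mk
  )
  dos <- dos[, match(genome$markers$id, colnames(dos)), drop = FALSE]
  het <- dos == 1
  if (any(het)) {
    if (strict) stop("heterozygous founder genotype found in strict mode")
    message(sum(het), " heterozygous call(s) rounded to a random homozygote")
    dos[het] <- 2L * rbinom(sum(het), 1L, 0.5)
  }
  if (!all(dos %in% c(0, 2))) stop("dosages must be 0 or 2 for homozygous founders")
  H <- matrix(as.integer(dos / 2), nrow = nrow(dos))
  pop <- bo_pop(genome, H, H, ids = rownames(dos), generation = 0L)
  list(genome = genome, pop = pop)
}

normalise_map_spec <- function(map_spec) {
  stopifnot(is.list(map_spec), all(c("markers", "chromosomes") %in% names(map_spec)))
  mk <- map_spec$markers
  ch <- map_spec$chromosomes
  if (is.character(mk)) mk <- read.csv(mk)
  if (is.character(ch)) ch <- read.csv(ch)
  stopifnot(all(c("marker", "chrom", "phys_pos") %in% names(mk)))
  stopifnot(all(c("chrom", "phys_len", "morgan_len") %in% names(ch)))
  mk$marker <- as.character(mk$marker); mk$chrom <- as.character(mk$chrom)
  ch$chrom <- as.character(ch$chrom)
  list(markers = mk, chromosomes = ch)
}

read_vcf_dosages <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF founders requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  if (any(lengths(VariantAnnotation::alt(vcf)) != 1L)) {
    stop("non-biallelic site in VCF")
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  count_alt <- function(g) {
    if (g %in% c("0/0", "0|0")) 0L
    else if (g %in% c("1/1", "1|1")) 2L
    else if (g %in% c("0/1", "1/0", "0|1", "1|0")) 1L
    else stop("unsupported GT field: ", g)
  }
  dos <- apply(gt, c(1, 2), count_alt)
  t(dos)  # individuals x markers
}

#' Write founders as a dosage CSV plus map CSVs
#'
#' Inverse of the CSV route of [load_founders()]; used for round-trip
#' checks and for exporting synthetic panels.
#'
#' @param pop a homozygous [bo_pop()].
#' @param geno_file,marker_file,chrom_file output CSV paths.
#' @param phys_scale physical length written per Morgan (default 1e6).
#' @return invisibly, the three paths.
#' @export
write_founders <- function(pop, geno_file, marker_file, chrom_file,
                           phys_scale = 1e6) {
  g <- pop$genome
  dos <- dosage_matrix(pop)
  out <- data.frame(id = pop$ids, dos, check.names = FALSE)
  colnames(out) <- c("id", g$markers$id)
  write.csv(out, geno_file, row.names = FALSE)
  write.csv(data.frame(marker = g$markers$id, chrom = g$markers$chrom,
                       phys_pos = g$markers$pos_m * phys_scale),
            marker_file, row.names = FALSE)
  write.csv(data.frame(chrom = g$chrom$name,
                       phys_len = g$chrom$length_m * phys_scale,
                       morgan_len = g$chrom$length_m),
            chrom_file, row.names = FALSE)
  invisible(c(geno_file, marker_file, chrom_file))
}
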