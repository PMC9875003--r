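# Shared fixture builders; everything is generated in code at test time.

# A tiny deterministic genome: n_chr chromosomes of 1 Morgan, markers at
# evenly spaced interior positions.
tiny_genome <- function(n_chr = 2L, snp_per_chr = 4L, length_m = 1) {
  chrom <- data.frame(name = paste0("chr", seq_len(n_chr)),
                      length_m = rep(length_m, n_chr))
  pos <- rep(seq_len(snp_per_chr) / (snp_per_chr + 1) * length_m, n_chr)
  markers <- data.frame(
    id = paste0("m", seq_len(n_chr * snp_per_chr)),
    chrom = rep(chrom$name, each = snp_per_chr),
    pos_m = pos
  )
  bo_genome(chrom, markers)
}

# A population from explicit dosage rows (homozygous: entries 0/2;
# heterozygous rows allowed via separate haplotypes).
pop_from_haplos <- function(genome, H1, H2, ids = NULL, generation = 0L) {
  if (is.null(ids)) ids <- sprintf("I%02d", seq_len(nrow(H1)))
  bo_pop(genome, H1, H2, ids = ids, generation = generation)
}

hom_pop <- function(genome, dosages, ids = NULL) {
  H <- dosages / 2
  storage.mode(H) <- "integer"
  pop_from_haplos(genome, H, H, ids)
}

# One-chromosome population with a single fully heterozygous individual,
# markers at given positions.
het_individual <- function(positions, length_m = 1) {
  chrom <- data.frame(name = "chr1", length_m = length_m)
  markers <- data.frame(id = paste0("m", seq_along(positions)),
                        chrom = "chr1", pos_m = positions)
  g <- bo_genome(chrom, markers)
  H1 <- matrix(1L, 1, length(positions))
  H2 <- matrix(0L, 1, length(positions))
  bo_pop(g, H1, H2, ids = "het1")
}

# Minimal uncompressed VCF with the given GT strings (markers x samples).
write_tiny_vcf <- function(path, gt, chrom = "chr1", pos = NULL,
                           ids = NULL) {
  n_mk <- nrow(gt); n_sm <- ncol(gt)
  if (is.null(pos)) pos <- seq_len(n_mk) * 1000L
  if (is.null(ids)) ids <- paste0("mk", seq_len(n_mk))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chrom, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", paste0("S", seq_len(n_sm))), collapse = "\t")
  )
  rows <- vapply(seq_len(n_mk), function(i) {
    paste(c(chrom, pos[i], ids[i], "A", "G", ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# Map spec matching a genome written by write_founders().
map_spec_for <- function(genome, phys_scale = 1e6) {
  list(
    markers = data.frame(marker = genome$markers$id,
                         chrom = genome$markers$chrom,
                         phys_pos = genome$markers$pos_m * phys_scale),
    chromosomes = data.frame(chrom = genome$chrom$name,
                             phys_len = genome$chrom$length_m * phys_scale,
                             morgan_len = genome$chrom$length_m)
  )
}
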