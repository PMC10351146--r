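#' Write and read PLINK ped/map text files
#'
#' `write_plink` writes whitespace-separated ped/map files with alleles coded
#' 1/2 (missing 0).  The two allele columns of a locus are written in
#' haplotype order, but ped format is unphased, so only the genotype matrix
#' round-trips; phase is not preserved by the format.  The map file carries
#' chromosome, locus id, genetic position in centimorgan and a synthetic
#' base-pair position.
#'
#' @param hap phased haplotype matrix (loci x 2n, alleles 0/1).
#' @param map locus map data.frame (`chrom`, `id`, `pos`).
#' @param path file prefix; `<path>.ped` and `<path>.map` are created.
#' @param ids individual ids (default 1..n).
#' @param sex sex codes (1 male, 2 female; default 0 = unknown).
#' @return `write_plink`: the prefix, invisibly.
#' @export
write_plink <- function(hap, map, path, ids = NULL, sex = NULL) {
  n <- ncol(hap) / 2
  if (is.null(ids)) ids <- seq_len(n)
  if (is.null(sex)) sex <- rep(0L, n)
  al <- hap + 1L  # 0/1 -> 1/2
  ped <- vapply(seq_len(n), function(i) {
    paste(c(ids[i], ids[i], 0L, 0L, sex[i], -9,
            as.vector(rbind(al[, 2 * i - 1], al[, 2 * i]))), collapse = " ")
  }, "")
  writeLines(ped, paste0(path, ".ped"))
  mp <- data.frame(map$chrom, map$id, map$pos * 100, seq_len(nrow(map)))
  write.table(mp, paste0(path, ".map"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_plink
#' @return `read_plink`: list with `geno` (loci x n dosage matrix of the
#'   counted allele "2"), `ids`, `sex` and `map`.
#' @export
read_plink <- function(path) {
  lines <- readLines(paste0(path, ".ped"))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (length(unique(nf)) != 1) stop("malformed ped: ragged line lengths")
  L <- (nf[1] - 6) / 2
  if (L != round(L)) stop("malformed ped: odd number of allele columns")
  mapdf <- read.table(paste0(path, ".map"),
                      col.names = c("chrom", "id", "cm", "bp"))
  if (nrow(mapdf) != L) stop("ped/map locus count mismatch")
  geno <- vapply(fields, function(f) {
    a <- as.integer(f[-(1:6)])
    if (any(!a %in% c(0L, 1L, 2L))) stop("allele codes must be 0, 1 or 2")
    a1 <- a[seq(1, 2 * L, 2)]; a2 <- a[seq(2, 2 * L, 2)]
    miss <- a1 == 0L | a2 == 0L
    out <- (a1 - 1L) + (a2 - 1L)
    out[miss] <- NA_integer_
    out
  }, integer(L))
  list(geno = geno,
       ids = vapply(fields, `[`, "", 2),
       sex = as.integer(vapply(fields, `[`, "", 5)),
       map = data.frame(chrom = mapdf$chrom, id = mapdf$id,
                        pos = mapdf$cm / 100))
}
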