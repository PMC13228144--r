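#' Read a genotype matrix from file
#'
#' Reads unlinked biallelic SNP genotypes from one of three plain-text
#' formats into a [genotype_matrix]:
#'
#' * `"vcf"`: VCF with a GT field. Only biallelic SNPs are accepted;
#'   multi-allelic or indel records are rejected with the offending locus
#'   named. Phased (`|`) and unphased (`/`) separators are both accepted;
#'   missing calls are `./.` (or `.`). Genotypes are coded as the count of
#'   the ALT allele. Parsing is delegated to \pkg{vcfR}.
#' * `"structure"`: two rows per individual, columns
#'   `sample_id population allele_1 ... allele_L`, preceded by a header row
#'   of locus ids. Alleles are integer codes, missing is -9; the genotype
#'   code is the count of the numerically larger ("second") allele at each
#'   locus. Allele code 1 is reserved for the reference allele, so a column
#'   monomorphic for code 2 reads back as genotype 2.
#' * `"matrix012"`: tab-separated 0/1/2 matrix with a header row of locus ids
#'   and a first column of sample ids; missing is `NA`.
#'
#' Row (individual) and column (locus) order follow the file.
#'
#' @param path Path to an existing file.
#' @param format One of `"vcf"`, `"structure"`, `"matrix012"`.
#' @param populations Optional character vector of population labels to
#'   attach (VCF and matrix012 carry none; default `"pop1"`).
#' @return A [genotype_matrix].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("vcf", "structure", "matrix012"),
                           populations = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gm <- switch(format,
    vcf = read_vcf_gt(path),
    structure = read_structure2(path),
    matrix012 = read_matrix012(path))
  if (!is.null(populations)) {
    stopifnot(length(populations) == length(gm$sample_ids))
    gm$populations <- as.character(populations)
    validate_genotype_matrix(gm)
  }
  gm
}

read_vcf_gt <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bad <- grepl(",", alt, fixed = TRUE)
  if (any(bad))
    stop("multi-allelic record(s) not supported: ",
         paste(ids[bad], collapse = ", "))
  bad <- nchar(ref) != 1L | nchar(alt) != 1L | is.na(alt)
  if (any(bad))
    stop("non-SNP (indel or missing ALT) record(s): ",
         paste(ids[bad], collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[gt == "0/0"] <- 0L
  code[gt == "0/1" | gt == "1/0"] <- 1L
  code[gt == "1/1"] <- 2L
  known <- is.na(gt) | gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (any(!known))
    stop("unparseable GT value(s), e.g. ", gt[!known][1])
  genotype_matrix(t(code), sample_ids = colnames(gt), locus_ids = ids)
}

read_structure2 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty STRUCTURE file")
  loci <- scan(text = lines[1], what = character(), quiet = TRUE)
  body <- lines[-1]
  if (length(body) %% 2L != 0L)
    stop("STRUCTURE file must have two rows per individual")
  toks <- lapply(body, function(x) scan(text = x, what = character(),
                                        quiet = TRUE))
  nf <- lengths(toks)
  if (any(nf != length(loci) + 2L))
    stop("ragged STRUCTURE rows: expected ", length(loci) + 2L,
         " fields, got ", paste(unique(nf[nf != length(loci) + 2L]),
                                collapse = ", "))
  m <- do.call(rbind, toks)
  n <- length(body) %/% 2L
  r1 <- m[2 * seq_len(n) - 1L, , drop = FALSE]
  r2 <- m[2 * seq_len(n), , drop = FALSE]
  if (any(r1[, 1] != r2[, 1]))
    stop("paired rows disagree on sample id")
  a1 <- matrix(as.integer(r1[, -(1:2), drop = FALSE]), nrow = n)
  a2 <- matrix(as.integer(r2[, -(1:2), drop = FALSE]), nrow = n)
  a1[a1 == -9L] <- NA_integer_
  a2[a2 == -9L] <- NA_integer_
  if (any(is.na(a1) != is.na(a2)))
    stop("half-missing genotypes (one allele -9) are not supported")
  code <- matrix(NA_integer_, n, length(loci))
  for (l in seq_along(loci)) {
    al <- sort(unique(c(a1[, l], a2[, l])))
    al <- al[!is.na(al)]
    if (length(al) > 2L)
      stop("more than two alleles at locus ", loci[l])
    second <- if (length(al) == 2L) al[2] else if (length(al) == 1L &&
      al[1] == 2L) 2L else NA_integer_
    if (length(al) == 0L) next
    if (is.na(second)) { code[, l] <- 0L; code[is.na(a1[, l]), l] <- NA }
    else code[, l] <- (a1[, l] == second) + (a2[, l] == second)
  }
  genotype_matrix(code, sample_ids = r1[, 1], populations = r1[, 2],
                  locus_ids = loci)
}

read_matrix012 <- function(path) {
  first <- readLines(path, n = 1L)
  header <- strsplit(first, "\t", fixed = TRUE)[[1]]
  nfield <- utils::count.fields(path, sep = "\t")
  if (any(nfield != length(header)))
    stop("ragged matrix012 file: rows with ",
         paste(unique(nfield[nfield != length(header)]), collapse = ", "),
         " fields, expected ", length(header))
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         colClasses = c("character",
                                        rep("integer", length(header) - 1L)))
  g <- as.matrix(d[, -1, drop = FALSE])
  genotype_matrix(g, sample_ids = d[[1]], locus_ids = header[-1])
}

#' Write a genotype matrix to file
#'
#' Writes a [genotype_matrix] in any of the formats accepted by
#' [read_genotypes()]. Output is bit-stable for identical input. The VCF
#' writer synthesizes placeholder CHROM (`"1"`) and POS (locus index) since
#' the loci are unlinked tags whose positions carry no meaning; locus ids go
#' in the ID column. STRUCTURE output codes alleles 1 (reference) and 2
#' (alternate) with missing -9. A zero-locus matrix yields a valid
#' header-only file.
#'
#' @param gm A [genotype_matrix].
#' @param path Output file path.
#' @param format One of `"vcf"`, `"structure"`, `"matrix012"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path,
                            format = c("vcf", "structure", "matrix012")) {
  format <- match.arg(format)
  validate_genotype_matrix(gm)
  switch(format,
    vcf = write_vcf_gt(gm, path),
    structure = write_structure2(gm, path),
    matrix012 = write_matrix012(gm, path))
  invisible(path)
}

write_vcf_gt <- function(gm, path) {
  g <- gm$genotypes
  header <- c("##fileformat=VCFv4.2",
              "##source=selfpop",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  L <- ncol(g)
  if (L) {
    gtmap <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_len(L), function(l) {
      calls <- ifelse(is.na(g[, l]), "./.", gtmap[g[, l] + 1L])
      paste(c("1", l, gm$locus_ids[l], "A", "T", ".", "PASS", ".", "GT",
              calls), collapse = "\t")
    }, character(1))
  } else body <- character(0)
  writeLines(c(header, body), path)
}

write_structure2 <- function(gm, path) {
  g <- gm$genotypes
  n <- nrow(g)
  out <- character(1L + 2L * n)
  out[1] <- paste(gm$locus_ids, collapse = "\t")
  for (i in seq_len(n)) {
    a1 <- ifelse(is.na(g[i, ]), -9L, ifelse(g[i, ] >= 1L, 2L, 1L))
    a2 <- ifelse(is.na(g[i, ]), -9L, ifelse(g[i, ] == 2L, 2L, 1L))
    pre <- paste(gm$sample_ids[i], gm$populations[i], sep = "\t")
    out[2 * i] <- paste(c(pre, a1), collapse = "\t")
    out[2 * i + 1] <- paste(c(pre, a2), collapse = "\t")
  }
  writeLines(out, path)
}

write_matrix012 <- function(gm, path) {
  d <- data.frame(sample_id = gm$sample_ids, check.names = FALSE)
  g <- gm$genotypes
  colnames(g) <- gm$locus_ids
  d <- cbind(d, as.data.frame(g, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a site-frequency spectrum
#'
#' A folded SFS is stored as a single line of whitespace-separated counts,
#' bin 0 (monomorphic) through bin `floor(n_alleles / 2)`.
#'
#' @param sfs A `folded_sfs` object (see [folded_sfs()]).
#' @param path File path.
#' @return `write_sfs()` returns `path` invisibly; `read_sfs()` returns a
#'   numeric vector of counts named by minor-allele count.
#' @export
write_sfs <- function(sfs, path) {
  writeLines(paste(format(sfs$counts, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  names(x) <- seq_along(x) - 1L
  x
}
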