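#' Write a PLINK bed/bim/fam fileset
#'
#' Binary PLINK output in the canonical SNP-major layout: the .bed file
#' starts with the magic bytes 0x6C 0x1B and mode byte 0x01, followed by
#' one record of `ceiling(n/4)` bytes per SNP. Two-bit codes follow the
#' PLINK convention (00 = homozygous A1 = dosage 2, 01 = missing,
#' 10 = heterozygous, 11 = homozygous A2 = dosage 0), packed
#' little-endian: the first sample occupies the lowest two bits. The .bim
#' and .fam companions are whitespace-delimited text in PLINK column
#' order; positions are 1-based.
#'
#' @param g Dosage matrix (SNPs x individuals), dosages counting A1.
#' @param panel `snp_panel` data frame aligned with the rows of `g`.
#' @param ped Pedigree data frame aligned with the columns of `g`.
#' @param prefix Output path prefix (directory must exist).
#' @return Invisibly, a list of class `bfile_set` with the three paths.
#' @export
write_bfile <- function(g, panel, ped, prefix) {
  if (ncol(g) == 0 || nrow(g) == 0) stop("refusing to write an empty fileset")
  stopifnot(nrow(panel) == nrow(g), nrow(ped) == ncol(g))
  n <- ncol(g)
  m <- nrow(g)
  codes <- matrix(3L, m, n)              # 11 = hom A2 (dosage 0)
  codes[g == 2L] <- 0L                   # 00 = hom A1
  codes[g == 1L] <- 2L                   # 10 = het
  codes[is.na(g)] <- 1L                  # 01 = missing
  pad <- (4 - n %% 4) %% 4
  if (pad) codes <- cbind(codes, matrix(0L, m, pad))
  blocks <- array(t(codes), dim = c(4, (n + pad) / 4, m))
  bytes <- blocks[1, , ] + blocks[2, , ] * 4L + blocks[3, , ] * 16L +
    blocks[4, , ] * 64L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  bim <- data.frame(chrom = panel$chrom, snp = panel$snp, cm = 0,
                    pos = panel$pos, a1 = panel$a1, a2 = panel$a2)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  sex_code <- ifelse(ped$sex == "male", 1L, ifelse(ped$sex == "female", 2L, 0L))
  fam <- data.frame(family = ped$family %||% ped$id,
                    id = ped$id,
                    father = ifelse(is.na(ped$father), "0", ped$father),
                    mother = ifelse(is.na(ped$mother), "0", ped$mother),
                    sex = sex_code, phen = -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(structure(list(bed = paste0(prefix, ".bed"),
                           bim = paste0(prefix, ".bim"),
                           fam = paste0(prefix, ".fam"),
                           snp_major = TRUE),
                      class = "bfile_set"))
}

#' Read a PLINK bed/bim/fam fileset
#'
#' Decodes the SNP-major binary layout written by [write_bfile()] (or
#' PLINK itself). Validates the magic bytes and the record length implied
#' by the .fam/.bim line counts.
#'
#' @param prefix Path prefix of the .bed/.bim/.fam triplet.
#' @return A list: `g` (dosage matrix, SNPs x individuals, counting A1),
#'   `panel` (`snp_panel`-shaped data frame), `fam` (sample registry).
#' @export
read_bfile <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing file(s): ", paste(missing, collapse = ", "))
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp", "cm", "pos", "a1", "a2"))
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("family", "id", "father", "mother",
                                  "sex", "phen"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  bpr <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpr * m) {
    stop("truncated .bed: expected ", bpr * m, " data bytes, found ",
         length(body))
  }
  ints <- as.integer(body)
  # unpack 2-bit fields, lowest bits first
  two_bits <- rbind(ints %% 4L,
                    (ints %/% 4L) %% 4L,
                    (ints %/% 16L) %% 4L,
                    (ints %/% 64L) %% 4L)
  codes <- matrix(two_bits, nrow = 4 * bpr)[seq_len(n), , drop = FALSE]
  lookup <- c(2L, NA_integer_, 1L, 0L)   # code 0,1,2,3 -> dosage
  g <- matrix(lookup[t(codes) + 1L], nrow = m, ncol = n)
  dimnames(g) <- list(bim$snp, fam$id)
  panel <- data.frame(snp = bim$snp, chrom = bim$chrom, pos = bim$pos,
                      a1 = bim$a1, a2 = bim$a2, freq = allele_freq(g),
                      stringsAsFactors = FALSE)
  class(panel) <- c("snp_panel", "data.frame")
  list(g = g, panel = panel, fam = fam)
}
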