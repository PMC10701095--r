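# EIGENSTRAT triplet I/O (ASCII geno dialect).
#
# .geno: one line per SNP, one digit per individual (0/1/2 derived-allele
#        count, 9 = missing). The packed binary dialect (magic "GENO") is
#        detected and rejected.
# .snp : snp_id  chrom  genetic_pos(Morgans)  pos_bp  ref  alt
# .ind : ind_id  sex  population [pseudohaploid-flag]
#        The optional 4th column ("PH"/"1"/"TRUE") marks pseudo-haploid
#        individuals; the format has no standard slot for this.

#' Read an EIGENSTRAT geno/snp/ind triplet
#'
#' @param prefix path prefix; \code{<prefix>.geno}, \code{.snp}, \code{.ind}
#'   are read. Alternatively pass the three paths explicitly.
#' @param geno_path,snp_path,ind_path explicit file paths (override prefix).
#' @return a \linkS4class{GenotypeTable}. Genotype code 9 becomes NA. The
#'   .snp genetic-position column (Morgans) is stored as cM; a column of all
#'   zeros is treated as "no map".
#' @export
readEigenstrat <- function(prefix = NULL, geno_path = NULL, snp_path = NULL,
                           ind_path = NULL) {
  if (!is.null(prefix)) {
    if (is.null(geno_path)) geno_path <- paste0(prefix, ".geno")
    if (is.null(snp_path)) snp_path <- paste0(prefix, ".snp")
    if (is.null(ind_path)) ind_path <- paste0(prefix, ".ind")
  }
  for (p in c(geno_path, snp_path, ind_path))
    if (!file.exists(p)) stop("file not found: ", p)
  head4 <- readBin(geno_path, "raw", 4L)
  if (identical(rawToChar(head4), "GENO"))
    stop("packed binary geno files are not supported; convert to ASCII geno")

  snp <- read.table(snp_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(snp) < 4L) stop("malformed .snp file: expected >= 4 columns")
  colnames(snp)[1:4] <- c("snp_id", "chrom", "gpos", "pos")
  ref <- if (ncol(snp) >= 6L) snp[[5]] else rep("A", nrow(snp))
  alt <- if (ncol(snp) >= 6L) snp[[6]] else rep("C", nrow(snp))

  ind <- read.table(ind_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ind) < 3L) stop("malformed .ind file: expected >= 3 columns")
  colnames(ind)[1:3] <- c("ind_id", "sex", "pop")
  ph <- if (ncol(ind) >= 4L)
    toupper(as.character(ind[[4]])) %in% c("PH", "1", "TRUE", "PSEUDOHAPLOID")
  else rep(FALSE, nrow(ind))

  lines <- readLines(geno_path)
  if (length(lines) != nrow(snp))
    stop(sprintf("dimension mismatch: %d geno rows but %d .snp rows",
                 length(lines), nrow(snp)))
  wid <- nchar(lines)
  if (any(wid != nrow(ind)))
    stop(sprintf("dimension mismatch at geno row %d: %d columns but %d individuals",
                 which(wid != nrow(ind))[1], wid[which(wid != nrow(ind))[1]],
                 nrow(ind)))
  g <- matrix(utf8ToInt(paste(lines, collapse = "")) - 48L,
              nrow = nrow(ind), ncol = length(lines))
  g <- t(g)
  if (any(!(g %in% c(0L, 1L, 2L, 9L))))
    stop("invalid genotype code in geno file (expected 0/1/2/9)")
  ord <- order(factor(snp$chrom, levels = unique(snp$chrom)), snp$pos)
  if (any(diff(ord) != 1L)) stop("unsorted .snp file: positions must increase within chromosome")
  gmap <- as.numeric(snp$gpos) * 100  # Morgans -> cM
  if (all(gmap == 0)) gmap <- rep(NA_real_, nrow(snp))
  GenotypeTable(calls = g, chrom = snp$chrom, pos_bp = snp$pos,
                ind_id = ind$ind_id, pop = ind$pop, pseudohaploid = ph,
                snp_id = snp$snp_id, ref = ref, alt = alt, gcM = gmap)
}

#' Write a GenotypeTable as an EIGENSTRAT triplet (ASCII geno)
#'
#' Pseudo-haploid status is written as a 4th .ind column ("PH").
#'
#' @param gt a \linkS4class{GenotypeTable}
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
writeEigenstrat <- function(gt, prefix) {
  g <- calls(gt)
  g[is.na(g)] <- 9L
  lines <- apply(g, 1L, function(r) intToUtf8(r + 48L))
  writeLines(lines, paste0(prefix, ".geno"))
  gm <- rowRanges(gt)$gcM
  gm[is.na(gm)] <- 0
  snp <- data.frame(rowRanges(gt)$snp_id, snpChrom(gt),
                    format(gm / 100, scientific = FALSE, trim = TRUE),
                    snpPos(gt), rowRanges(gt)$ref, rowRanges(gt)$alt)
  write.table(snp, paste0(prefix, ".snp"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  ind <- data.frame(colnames(gt), "U", indPop(gt),
                    ifelse(isPseudohaploid(gt), "PH", "D"))
  write.table(ind, paste0(prefix, ".ind"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".geno", ".snp", ".ind")))
}
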