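#' Read genotypes from VCF or a matrix + map file pair
#'
#' Two dialects are supported.  `format = "matrix"` reads a whitespace
#' delimited n x p integer table of \{0, 1, 2\} codes plus a 3-column map file
#' (`marker_id chrom pos`).  `format = "vcf"` reads a VCF and codes genotypes
#' as the number of copies of the alternate allele; multi-allelic sites and
#' non-SNP records are excluded and reported.
#'
#' @param path path to the genotype matrix file or the VCF.
#' @param format `"matrix"` or `"vcf"`.
#' @param mapPath map file (required for `format = "matrix"`).
#' @param sampleIds optional sample ids for matrix input (one per row).
#' @param impute how to handle missing genotype calls: `"error"` (default),
#'   `"mode"` (per-marker modal code, suited to inbred panels) or `"mean"`
#'   (per-marker mean rounded to the nearest valid code).
#'
#' @return a [GenotypeData-class] object.  For VCF input the ids of excluded
#'   (non-biallelic / non-SNP) records are attached as
#'   `attr(x, "excludedMarkers")`.
#' @export
readGenotypes <- function(path, format = c("matrix", "vcf"), mapPath = NULL,
                          sampleIds = NULL,
                          impute = c("error", "mode", "mean")) {
  format <- match.arg(format)
  impute <- match.arg(impute)
  if (format == "matrix") {
    if (is.null(mapPath)) stop("matrix format requires a mapPath")
    codes <- tryCatch(
      as.matrix(utils::read.table(path, header = FALSE)),
      error = function(e) stop("failed to parse genotype matrix '", path,
                               "': ", conditionMessage(e)))
    map <- utils::read.table(mapPath, header = FALSE,
                             col.names = c("marker_id", "chrom", "pos"))
    if (ncol(codes) != nrow(map))
      stop("genotype matrix has ", ncol(codes), " columns but map lists ",
           nrow(map), " markers")
    bad <- which(!(codes %in% c(0, 1, 2)) & !is.na(codes))
    if (length(bad))
      stop("invalid genotype code at matrix entry ", bad[1],
           " (row ", row(codes)[bad[1]], "): codes must be 0/1/2")
    codes <- imputeMissing(codes, impute)
    return(GenotypeData(codes, map, sampleIds = sampleIds))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  excluded <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                     paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  excluded <- excluded[!snp]
  if (length(excluded))
    message(length(excluded),
            " non-biallelic/non-SNP record(s) excluded from VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  # count alternate-allele copies; accept phased or unphased separators
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  codes <- matrix(suppressWarnings(as.numeric(a1) + as.numeric(a2)),
                  nrow = nrow(gt), dimnames = dimnames(gt))
  codes <- t(codes)  # samples x markers
  if (any(!is.na(codes) & !(codes %in% c(0, 1, 2))))
    stop("VCF contains genotype codes outside 0/1/2 after alt-allele counting")
  codes <- imputeMissing(codes, impute)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  map <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]))
  out <- GenotypeData(codes, map)
  attr(out, "excludedMarkers") <- excluded
  out
}

imputeMissing <- function(codes, impute) {
  miss <- is.na(codes)
  if (!any(miss)) return(codes)
  if (impute == "error") {
    j <- which(colSums(miss) > 0)[1]
    stop("missing genotype calls (e.g. marker column ", j, "); rerun with ",
         "impute = 'mode' or 'mean' to fill them explicitly")
  }
  for (j in which(colSums(miss) > 0)) {
    obs <- codes[!miss[, j], j]
    if (!length(obs)) stop("marker column ", j, " has no observed calls")
    fill <- if (impute == "mode") {
      as.numeric(names(which.max(table(obs))))
    } else {
      f <- round(mean(obs))
      min(max(f, 0), 2)
    }
    codes[miss[, j], j] <- fill
  }
  codes
}

#' Write genotypes in the matrix + map dialect
#'
#' @param g a [GenotypeData-class] object.
#' @param path genotype matrix file to write.
#' @param mapPath map file to write.
#' @return invisibly, the paths written.
#' @export
writeGenotypes <- function(g, path, mapPath) {
  utils::write.table(genoCodes(g), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(markerMap(g)[, c("marker_id", "chrom", "pos")], mapPath,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(path, mapPath))
}

#' Read a two-column phenotype table and align it to a genotype panel
#'
#' Expects a header line and two columns (sample id, trait value), comma or
#' tab/space separated.  When `genotypes` is supplied the returned vector is
#' ordered like `sampleIds(genotypes)`, with `NA` for samples lacking a
#' phenotype; phenotype ids absent from the panel are reported in
#' `attr(x, "unmatched")`.
#'
#' @param path phenotype file.
#' @param genotypes optional [GenotypeData-class] panel to align against.
#' @return named numeric vector of trait values.
#' @export
readPhenotypes <- function(path, genotypes = NULL) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("phenotype file must have two columns (id, value)")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate phenotype ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- suppressWarnings(as.numeric(tab[[2]]))
  bad <- which(is.na(vals) & !is.na(tab[[2]]))
  if (length(bad))
    stop("non-numeric phenotype value '", tab[[2]][bad[1]], "' at data row ",
         bad[1])
  names(vals) <- ids
  if (is.null(genotypes)) return(vals)
  panel <- sampleIds(genotypes)
  out <- vals[match(panel, ids)]
  names(out) <- panel
  attr(out, "unmatched") <- setdiff(ids, panel)
  attr(out, "missingPhenotype") <- panel[is.na(out)]
  out
}

#' Resolve linkage phase, assigning heterozygous loci at random
#'
#' Homozygous loci are phased deterministically (both chromosome copies carry
#' the same allele).  Each heterozygous locus is independently oriented with
#' probability 1/2, i.e. the counted allele is placed on the maternal copy
#' with 50% probability, matching the treatment of unknown-phase panels in
#' haplotype-based prediction.  Loci are visited in map order so a fixed seed
#' yields a reproducible phasing.
#'
#' @param g a [GenotypeData-class] object.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a [PhasedGenotypes-class] object whose maternal + paternal
#'   matrices sum exactly to `genoCodes(g)`.
#' @export
assignRandomPhase <- function(g, seed = NULL) {
  codes <- genoCodes(g)
  mat <- codes / 2           # exact for 0 and 2
  het <- codes == 1
  if (any(het)) {
    draws <- withSeed(seed, {
      # visit markers in map order, individuals within marker
      stats::rbinom(sum(het), 1, 0.5)
    })
    # column-major order of `which` matches (marker, individual) traversal
    mat[which(het)] <- draws
  }
  PhasedGenotypes(mat, codes - mat, markerMap(g))
}
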