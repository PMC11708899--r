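#' Genotype matrices and EIGENSTRAT text IO
#'
#' A `geno_matrix` holds per-sample, per-SNP genotype calls coded 0/1/2
#' (count of the alternative allele) with `NA` for missing data.
#' Pseudo-haploid samples -- where a single randomly drawn sequencing read
#' stands in for the diploid genotype -- carry only the homozygous codes
#' 0 and 2. The object bundles the call matrix (samples x SNPs) with a SNP
#' registry and per-sample ploidy mode.
#'
#' @param calls integer matrix, samples in rows, SNPs in columns; values in
#'   \{0, 1, 2, NA\}.
#' @param snps data frame with columns `id`, `chrom`, `gpos` (genetic
#'   position, morgans; may be NA), `pos` (1-based physical position),
#'   `ref`, `alt`.
#' @param samples character vector of sample identifiers (row names).
#' @param ploidy character vector, one of `"diploid"` or `"pseudohaploid"`
#'   per sample, recycled if length 1.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, snps, samples, ploidy = "diploid") {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (length(samples) != nrow(calls))
    stop("number of samples does not match call matrix rows")
  if (nrow(snps) != ncol(calls))
    stop("SNP registry does not match call matrix columns")
  ploidy <- rep_len(as.character(ploidy), length(samples))
  if (!all(ploidy %in% c("diploid", "pseudohaploid")))
    stop("ploidy must be 'diploid' or 'pseudohaploid'")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  het <- which(ploidy == "pseudohaploid" & apply(calls == 1L, 1, any, na.rm = TRUE))
  if (length(het))
    stop("pseudo-haploid sample(s) contain heterozygous calls: ",
         paste(samples[het], collapse = ", "))
  rownames(calls) <- samples
  colnames(calls) <- snps$id
  structure(list(calls = calls, snps = as.data.frame(snps),
                 samples = as.character(samples), ploidy = ploidy),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d SNPs (%.1f%% missing)\n",
              length(x$samples), nrow(x$snps),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

.canon_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  chrom[chrom == "23"] <- "X"
  chrom[chrom == "24"] <- "Y"
  chrom
}

#' Read an EIGENSTRAT genotype triplet
#'
#' Reads the text (`0129`) dialect of the EIGENSTRAT format: a `.geno` file
#' with one row per SNP and one character per individual, a `.snp` registry
#' and a `.ind` sample file. Character `9` maps to missing. Chromosomes 23
#' and 24 are canonicalised to `X` and `Y`.
#'
#' @param geno_path,snp_path,ind_path paths to the three files.
#' @param ploidy per-sample ploidy mode; the EIGENSTRAT format does not
#'   record it, so the default `"infer"` marks a sample pseudo-haploid when
#'   it carries no heterozygous call.
#' @return A [geno_matrix()]. The `.ind` sex and group columns are attached
#'   as attributes `sex` and `group`.
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path, ploidy = "infer") {
  lines <- readLines(geno_path)
  if (!length(lines)) stop("empty geno file: ", geno_path)
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged geno rows in %s: line %d has width %d, expected %d",
                 geno_path, which(widths != widths[1])[1],
                 widths[widths != widths[1]][1], widths[1]))
  ind <- utils::read.table(ind_path, header = FALSE,
                           col.names = c("id", "sex", "group"),
                           stringsAsFactors = FALSE)
  snp <- utils::read.table(snp_path, header = FALSE,
                           col.names = c("id", "chrom", "gpos", "pos", "ref", "alt"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  snp$chrom <- .canon_chrom(snp$chrom)
  if (length(lines) != nrow(snp))
    stop(sprintf("geno has %d rows but snp file has %d entries",
                 length(lines), nrow(snp)))
  if (widths[1] != nrow(ind))
    stop(sprintf("geno rows have %d characters but ind file has %d samples",
                 widths[1], nrow(ind)))
  chars <- strsplit(paste(lines, collapse = ""), "", fixed = TRUE)[[1]]
  code <- match(chars, c("0", "1", "2", "9")) - 1L
  if (anyNA(code)) {
    k <- which(is.na(code))[1]
    stop(sprintf("invalid genotype character '%s' in %s at line %d, column %d",
                 chars[k], geno_path,
                 (k - 1L) %/% widths[1] + 1L, (k - 1L) %% widths[1] + 1L))
  }
  code[code == 3L] <- NA_integer_
  # geno lines are SNP-major; column-major fill gives samples x snps directly
  calls <- matrix(code, nrow = widths[1], ncol = length(lines))
  if (identical(ploidy, "infer")) {
    ploidy <- ifelse(apply(calls == 1L, 1, any, na.rm = TRUE),
                     "diploid", "pseudohaploid")
  }
  g <- geno_matrix(calls, snp, ind$id, ploidy)
  attr(g, "sex") <- ind$sex
  attr(g, "group") <- ind$group
  g
}

#' Write an EIGENSTRAT genotype triplet
#'
#' @param mat a [geno_matrix()].
#' @param out_prefix path prefix; `.geno`, `.snp`, `.ind` are appended.
#' @param sex,group optional per-sample columns for the `.ind` file;
#'   default `U` / `Control`.
#' @return Invisibly, the three file paths.
#' @export
write_eigenstrat <- function(mat, out_prefix, sex = NULL, group = NULL) {
  stopifnot(inherits(mat, "geno_matrix"))
  if (!length(mat$samples)) stop("refusing to write a matrix with no samples")
  calls <- mat$calls
  calls[is.na(calls)] <- 9L
  geno_lines <- apply(calls, 2, paste, collapse = "")  # one row per SNP
  paths <- paste0(out_prefix, c(".geno", ".snp", ".ind"))
  writeLines(geno_lines, paths[1])
  snp <- mat$snps
  snp$gpos[is.na(snp$gpos)] <- 0
  utils::write.table(
    data.frame(snp$id, snp$chrom, format(snp$gpos, scientific = FALSE),
               snp$pos, snp$ref, snp$alt),
    paths[2], quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  if (is.null(sex)) sex <- rep("U", length(mat$samples))
  if (is.null(group)) group <- rep("Control", length(mat$samples))
  utils::write.table(data.frame(mat$samples, sex, group),
                     paths[3], quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(paths)
}

#' Parse a calendar date-range string
#'
#' Accepts the dialects used in ancient-DNA sample tables:
#' `"1873-1566 cal BCE"`, `"1600-1800 CE"`, `"150-1 BCE"` and mixed-era
#' `"400 BCE-100 CE"` forms, with en-dash or hyphen. Years are returned on
#' the signed axis (BCE negative, CE positive); a `cal` token marks a
#' calibrated radiocarbon range.
#'
#' @param text character vector of date-range strings.
#' @return Data frame with columns `date_lo`, `date_hi`, `is_calibrated`.
#' @export
parse_date_range <- function(text) {
  parse1 <- function(s0) {
    s <- gsub("–|—", "-", trimws(s0))
    s <- gsub("\\s+", " ", s)
    cal <- grepl("\\bcal\\b", s)
    s <- trimws(gsub("\\bcal\\b", "", s))
    s <- gsub("\\s+", " ", s)
    one_era <- "^([0-9]+) ?- ?([0-9]+) (BCE|CE)$"
    mixed <- "^([0-9]+) (BCE|CE) ?- ?([0-9]+) (BCE|CE)$"
    if (grepl(one_era, s)) {
      m <- regmatches(s, regexec(one_era, s))[[1]]
      sgn <- if (m[4] == "BCE") -1 else 1
      yrs <- sort(sgn * as.numeric(m[2:3]))
    } else if (grepl(mixed, s)) {
      m <- regmatches(s, regexec(mixed, s))[[1]]
      a <- as.numeric(m[2]) * (if (m[3] == "BCE") -1 else 1)
      b <- as.numeric(m[4]) * (if (m[5] == "BCE") -1 else 1)
      yrs <- sort(c(a, b))
    } else {
      stop("unrecognised date range: '", s0, "'")
    }
    c(yrs, cal)
  }
  out <- t(vapply(text, parse1, numeric(3)))
  data.frame(date_lo = out[, 1], date_hi = out[, 2],
             is_calibrated = as.logical(out[, 3]), row.names = NULL)
}

#' Read a sample-metadata table
#'
#' Reads a tab-separated metadata table with one row per individual:
#' identifier, site, region, group label, textual date range, genetic sex,
#' coverage, and optionally uniparental haplogroups and site coordinates.
#' Date ranges are parsed with [parse_date_range()] and the midpoint
#' `date_mid` is added.
#'
#' @param tsv_path path to the TSV file (header required).
#' @return Data frame with one record per individual.
#' @export
read_sample_metadata <- function(tsv_path) {
  md <- utils::read.delim(tsv_path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("id", "site", "region", "group", "date_text", "sex", "coverage")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dates <- parse_date_range(md$date_text)
  md$date_lo <- dates$date_lo
  md$date_hi <- dates$date_hi
  md$is_calibrated <- dates$is_calibrated
  md$date_mid <- (md$date_lo + md$date_hi) / 2
  if (any(md$coverage < 0, na.rm = TRUE)) stop("negative coverage in metadata")
  md
}

#' Load the packaged North Pontic cohort metadata
#'
#' Metadata for the 91-individual ancient cohort from present-day Ukraine
#' that the package's analyses are designed around: site, region,
#' archaeological group label, date range (calibrated where marked), genetic
#' sex, uniparental haplogroups and mean genomic coverage. Site coordinates
#' are approximate site locations added for the geographic matching
#' analyses.
#'
#' @return Data frame of 91 records (see [read_sample_metadata()]).
#' @export
load_north_pontic_metadata <- function() {
  read_sample_metadata(system.file("extdata", "north_pontic_individuals.tsv",
                                   package = "ancientpop", mustWork = TRUE))
}

#' Individuals excluded from the date-binned heterogeneity analysis
#'
#' Four genomes fall outside the four analysis date ranges (one Neolithic,
#' two Scythian-period, one Antiquity-associated) and are excluded by
#' identifier rather than by midpoint logic.
#'
#' @format Character vector of four sample identifiers.
#' @export
north_pontic_exclusions <- c("UKR008", "UKR095", "UKR096", "UKR153")

#' Drop samples with too few covered SNPs
#'
#' Sample-level QC: removes samples whose number of non-missing calls falls
#' below `min_snps` (e.g. 10,000 for broad autosomal analyses, 100,000 for
#' admixture modelling).
#'
#' @param mat a [geno_matrix()].
#' @param min_snps minimum number of non-missing calls to keep a sample.
#' @return Filtered `geno_matrix`; dropped identifiers are attached as
#'   attribute `dropped` and reported via `message()`.
#' @export
filter_samples_by_snp_overlap <- function(mat, min_snps) {
  stopifnot(inherits(mat, "geno_matrix"), min_snps >= 0)
  n_obs <- rowSums(!is.na(mat$calls))
  keep <- n_obs >= min_snps
  dropped <- mat$samples[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " sample(s) with <", min_snps,
            " SNPs: ", paste(dropped, collapse = ", "))
  out <- geno_matrix(mat$calls[keep, , drop = FALSE], mat$snps,
                     mat$samples[keep], mat$ploidy[keep])
  for (a in c("sex", "group"))
    if (!is.null(attr(mat, a))) attr(out, a) <- attr(mat, a)[keep]
  attr(out, "dropped") <- dropped
  out
}
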