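#' OTU count/fraction table
#'
#' Lightweight container for a samples-by-OTUs abundance matrix. Rows are
#' samples, columns are OTUs. The `unit` flag records whether entries are
#' sequencing read counts (`"counts"`) or row-relative fractions
#' (`"fraction"`, every row summing to 1).
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns, with
#'   unique row (sample) and column (OTU) names and no negative entries.
#' @param unit `"counts"` or `"fraction"`.
#' @return An object of class `otutab`: the validated matrix with a
#'   `unit` attribute.
#' @examples
#' m <- matrix(c(3, 1, 0, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' tab <- otutab(m)
#' relative_abundance(tab)
#' @export
otutab <- function(counts, unit = c("counts", "fraction")) {
  unit <- match.arg(unit)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in table")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (unit == "fraction") {
    rs <- rowSums(counts)
    if (any(abs(rs - 1) > 1e-9))
      stop("fraction table rows must sum to 1")
  }
  structure(counts, unit = unit, class = c("otutab", "matrix", "array"))
}

#' @export
print.otutab <- function(x, ...) {
  cat(sprintf("otutab: %d samples x %d OTUs (%s)\n",
              nrow(x), ncol(x), attr(x, "unit")))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE]))
  invisible(x)
}

#' @export
`[.otutab` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out))
    out <- structure(out, unit = attr(x, "unit"),
                     class = c("otutab", "matrix", "array"))
  out
}

table_unit <- function(x) attr(x, "unit")

#' Read an OTU table and its sample metadata
#'
#' The table is a UTF-8 tab-separated matrix whose header row holds OTU ids
#' and whose first column holds sample ids; the metadata file has one row
#' per sample with at least the columns `sample_id`, `lake`, `time_index`,
#' `season` and `missing`. Samples are returned in metadata order
#' (rows flagged `missing` have no count row).
#'
#' @param path path to the count TSV.
#' @param metadata_path path to the metadata TSV.
#' @return list with elements `table` (an [otutab]) and `metadata`
#'   (a data.frame).
#' @seealso [write_otutab()]
#' @export
read_otutab <- function(path, metadata_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count table needs a sample id column plus OTUs")
  sample_ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- sample_ids
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("metadata must have a sample_id column")
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  if (!"missing" %in% names(meta)) meta$missing <- FALSE
  meta$missing <- as.logical(meta$missing)
  present <- meta$sample_id[!meta$missing]
  absent <- setdiff(present, rownames(m))
  if (length(absent))
    stop("metadata samples missing from table: ", paste(absent, collapse = ", "))
  m <- m[present, , drop = FALSE]
  list(table = otutab(m), metadata = meta)
}

#' Write an OTU table (and optionally metadata) as TSV
#'
#' Deterministic column order (as stored); first column `sample_id`.
#'
#' @param table an [otutab].
#' @param path output TSV path.
#' @param metadata optional metadata data.frame written alongside.
#' @param metadata_path path for the metadata TSV (required if `metadata`
#'   is given).
#' @return `path`, invisibly.
#' @export
write_otutab <- function(table, path, metadata = NULL, metadata_path = NULL) {
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata)) {
    if (is.null(metadata_path)) stop("metadata_path required when writing metadata")
    utils::write.table(metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Rarefy a count table to even depth
#'
#' Each sample's reads are subsampled uniformly at random *without
#' replacement* (a hypergeometric draw per OTU) down to `depth`, the usual
#' normalisation to the read number of the shallowest sample. Each sample
#' gets its own RNG stream derived as `seed + sample position`, so the
#' result is reproducible and independent of which other samples are
#' present.
#'
#' @param table an [otutab] with `unit == "counts"`.
#' @param depth target depth; defaults to the minimum row sum.
#' @param seed integer master seed.
#' @return rarefied [otutab]; every row sums exactly to `depth`.
#' @export
rarefy_counts <- function(table, depth = NULL, seed = 1L) {
  if (table_unit(table) != "counts") stop("rarefaction needs a counts table")
  m <- unclass(table)
  if (any(m != round(m))) stop("rarefaction needs integer counts")
  rs <- rowSums(m)
  if (is.null(depth)) depth <- min(rs)
  depth <- as.integer(depth)
  if (depth <= 0) stop("depth must be positive")
  low <- rs < depth
  if (any(low))
    stop("depth ", depth, " exceeds read count of sample(s): ",
         paste(rownames(m)[low], collapse = ", "))
  out <- m
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    if (rs[i] == depth) next
    withr::with_seed(as.integer(seed) + i, {
      picked <- sample.int(rs[i], depth)
    })
    # map read indices back to OTUs via cumulative counts
    breaks <- c(0, cumsum(row))
    tab <- tabulate(findInterval(picked, breaks, left.open = TRUE),
                    nbins = ncol(m))
    out[i, ] <- tab
  }
  otutab(out)
}

#' Convert counts to row-relative abundances
#'
#' @param table an [otutab] with `unit == "counts"` and no all-zero rows.
#' @return an [otutab] with `unit == "fraction"`.
#' @export
relative_abundance <- function(table) {
  if (table_unit(table) == "fraction")
    stop("table is already in fractions")
  m <- unclass(table)
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("all-zero sample(s): ", paste(rownames(m)[rs == 0], collapse = ", "))
  otutab(m / rs, unit = "fraction")
}

#' Abundance/prevalence filter for network analysis
#'
#' Keeps OTUs that are both (a) strictly above `abun_threshold` relative
#' abundance in at least one sample and (b) present with strictly more than
#' `read_threshold` reads in at least `sample_min` samples; the defaults
#' (>1% in one sample, >10 reads in three subsampled samples) are the usual
#' complexity-reduction step before association testing. The sample set is
#' unchanged and the filter is idempotent.
#'
#' @param table rarefied [otutab] (counts).
#' @param abun_threshold relative-abundance cutoff (strict), default 0.01.
#' @param read_threshold read cutoff (strict), default 10.
#' @param sample_min minimum number of qualifying samples, default 3.
#' @return filtered [otutab] (possibly with zero OTUs).
#' @export
filter_for_network <- function(table, abun_threshold = 0.01,
                               read_threshold = 10, sample_min = 3) {
  if (table_unit(table) != "counts") stop("filter expects a counts table")
  m <- unclass(table)
  fr <- m / rowSums(m)
  keep_abund <- apply(fr, 2, function(col) any(col > abun_threshold))
  keep_reads <- colSums(m > read_threshold) >= sample_min
  table[, keep_abund & keep_reads]
}

#' Electrical conductivity to salinity
#'
#' Linear conversion from EC (mS/cm) to total dissolved ions (g/L) using a
#' regression published for soda lakes of the study region. The printed
#' intercept (179) implies at least 179 g/L at zero conductivity, which is
#' far above the subsaline-to-hyposaline range of these waters and is
#' likely a typographic slip (0.179 would be plausible); the conversion is
#' implemented exactly as printed but both coefficients are configurable,
#' and a warning flags the implausible default intercept.
#'
#' @param ec electrical conductivity in mS/cm, non-negative.
#' @param slope,intercept regression coefficients; defaults as published.
#' @param warn warn when the intercept implies >= 100 g/L at EC = 0.
#' @return salinity in g/L.
#' @examples
#' suppressWarnings(ec_to_salinity(10))   # 186.92
#' ec_to_salinity(10, intercept = 0.179)  # plausible variant
#' @export
ec_to_salinity <- function(ec, slope = 0.792, intercept = 179, warn = TRUE) {
  if (any(ec < 0)) stop("EC must be non-negative")
  if (warn && intercept >= 100)
    warning("intercept ", intercept,
            " g/L implies hypersaline water at EC = 0; ",
            "the published coefficient is used as printed, but consider 0.179")
  slope * ec + intercept
}
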