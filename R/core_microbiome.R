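#' Partition OTUs into core and non-core sets across lakes
#'
#' An OTU is *core* for a set of lakes when it is detected (at least one
#' read, pooled over all sampling occasions, after rarefaction) in every
#' lake of the set — e.g. "core5" for all five lakes of a study, "core4"
#' for the four lakes of one habitat type. Every other OTU detected in a
#' lake is non-core for that lake.
#'
#' @param tables named list lake -> [otutab] (rarefied counts).
#' @param lakes lakes to intersect over; default all of `names(tables)`.
#' @param label partition label, e.g. `"core5"`; default derived from the
#'   number of lakes.
#' @return object of class `core_partition`: list with `lakes_considered`,
#'   `core` (character vector), `noncore` (named list lake -> character),
#'   `label`.
#' @export
partition_core <- function(tables, lakes = names(tables), label = NULL) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("`tables` must be a named list of otutab objects")
  unknown <- setdiff(lakes, names(tables))
  if (length(unknown)) stop("unknown lake(s): ", paste(unknown, collapse = ", "))
  if (length(lakes) < 2) stop("need at least two lakes")
  detected <- lapply(tables[lakes], function(tb) {
    tot <- colSums(unclass(tb))
    names(tot)[tot > 0]
  })
  core <- Reduce(intersect, detected)
  noncore <- lapply(detected, function(d) setdiff(d, core))
  if (is.null(label)) label <- paste0("core", length(lakes))
  structure(list(lakes_considered = lakes, core = sort(core),
                 noncore = noncore, label = label),
            class = "core_partition")
}

#' @export
print.core_partition <- function(x, ...) {
  cat(sprintf("%s over {%s}: %d core OTUs\n", x$label,
              paste(x$lakes_considered, collapse = ", "), length(x$core)))
  invisible(x)
}

#' Share of reads contributed by a core set
#'
#' For each sample, the fraction of its reads belonging to the given core
#' OTU set (OTUs absent from the table contribute zero), plus the pooled
#' share over all reads of the table.
#'
#' @param table an [otutab] (counts) with no zero-read samples.
#' @param core character vector of core OTU ids (may include ids absent
#'   from the table).
#' @return list with `per_sample` (named numeric in \[0,1\]) and `pooled`
#'   (single fraction).
#' @export
core_contribution <- function(table, core) {
  m <- unclass(table)
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("zero-read sample(s): ", paste(rownames(m)[rs == 0], collapse = ", "))
  hit <- intersect(core, colnames(m))
  core_reads <- if (length(hit)) rowSums(m[, hit, drop = FALSE]) else
    stats::setNames(numeric(nrow(m)), rownames(m))
  list(per_sample = core_reads / rs, pooled = sum(core_reads) / sum(rs))
}

#' Export a core partition as a long table
#'
#' @param partition a `core_partition`.
#' @param path optional TSV path; when given, written and returned
#'   invisibly.
#' @return data.frame with columns `otu_id`, `label` (`"core"` or
#'   `"noncore:<lake>"`).
#' @export
core_partition_table <- function(partition, path = NULL) {
  rows <- data.frame(otu_id = partition$core,
                     label = rep("core", length(partition$core)),
                     stringsAsFactors = FALSE)
  for (lk in names(partition$noncore)) {
    nc <- partition$noncore[[lk]]
    if (length(nc))
      rows <- rbind(rows, data.frame(otu_id = nc,
                                     label = paste0("noncore:", lk),
                                     stringsAsFactors = FALSE))
  }
  if (!is.null(path)) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
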