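# Tab-separated I/O with a machine-readable provenance header.
#
# Every table the pipeline writes starts with a single comment line
# `# lhmap-provenance: {json}` carrying the root seed and a hash of the run
# configuration, so outputs are traceable to the exact run that made them.

provenance_line <- function(seed = NA, config = NULL) {
  # run-specific paths carry no scientific identity and would make otherwise
  # identical runs hash differently
  if (is.list(config))
    config <- config[setdiff(names(config),
                             c("out_dir", "behavior_tsv", "counts_tsv",
                               "centroids_tsv", "atlas_nrrd"))]
  hash <- if (is.null(config)) NA_character_ else
    # small polynomial hash over the serialized config; enough to
    # fingerprint a run
    {
      bytes <- utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                          digits = NA))
      h <- 0
      for (b in bytes) h <- (h * 31 + b) %% 2147483647
      sprintf("%08x", as.integer(h))
    }
  paste0("# lhmap-provenance: ",
         jsonlite::toJSON(list(seed = seed, config_hash = hash,
                               package = "lhmap",
                               version = as.character(utils::packageVersion("lhmap"))),
                          auto_unbox = TRUE, null = "null"))
}

#' Write a data.frame as TSV with a provenance header
#'
#' @param x data.frame.
#' @param path output file (UTF-8, tab-delimited, `.` decimal separator).
#' @param seed,config recorded in the provenance comment line.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, seed = NA, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_line(seed, config), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (or any tab-delimited file)
#'
#' @param path input file; `#`-prefixed lines are ignored.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed TSV in ", path, ": ",
                             conditionMessage(e)))
  out
}

#' Read a region-count matrix with its pair design
#'
#' Expects the layout written by the pipeline: columns `animal_id`,
#' `pair_id`, `group`, then one column per region acronym.
#'
#' @param path region-count TSV.
#' @return list with `counts` (integer matrix) and `design` (data.frame).
#' @export
read_region_counts <- function(path) {
  x <- read_tsv(path)
  need <- c("animal_id", "pair_id", "group")
  if (!all(need %in% names(x)))
    stop("region-count TSV ", path, " must carry columns ",
         paste(need, collapse = ", "))
  counts <- as.matrix(x[, setdiff(names(x), need), drop = FALSE])
  rownames(counts) <- x$animal_id
  storage.mode(counts) <- "integer"
  list(counts = counts, design = x[, need])
}

write_region_counts <- function(counts, design, path, seed = NA, config = NULL) {
  write_tsv(cbind(design, as.data.frame(counts[design$animal_id, , drop = FALSE])),
            path, seed = seed, config = config)
}
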