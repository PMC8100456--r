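#' Construct a PRE intensity-ratio dataset
#'
#' Paramagnetic relaxation enhancement (PRE) data: per-residue
#' paramagnetic/diamagnetic peak intensity ratios `I_para/I_dia` measured for
#' one or more nitroxide spin-label sites.
#'
#' @param data data frame with columns `label_site` (residue index of the
#'   paramagnetic centre), `residue` (observed amide residue index), `ratio`
#'   (dimensionless, typically in `[0, ~1]`) and `error`.
#' @param n_residues optional chain length used to validate that label sites
#'   lie within the protein.
#' @return An object of class `pre_dataset` (also a data frame).
#' @export
pre_dataset <- function(data, n_residues = NULL) {
  .assert(is.data.frame(data), "data must be a data frame")
  needed <- c("label_site", "residue", "ratio", "error")
  missing <- setdiff(needed, names(data))
  .assert(length(missing) == 0, "missing PRE column(s): %s",
          paste(missing, collapse = ", "))
  .assert(all(is.finite(data$ratio)), "PRE ratios must be finite")
  .assert(all(is.finite(data$error) & data$error > 0), "PRE errors must be positive")
  key <- paste(data$label_site, data$residue)
  dup <- duplicated(key)
  .assert(!any(dup), "duplicate (label_site, residue) row: %s", key[dup][1])
  if (!is.null(n_residues)) {
    .assert(all(data$label_site >= 1 & data$label_site <= n_residues),
            "label_site outside protein range 1..%d", n_residues)
  }
  data <- data[order(data$label_site, data$residue), needed]
  rownames(data) <- NULL
  structure(data, class = c("pre_dataset", "data.frame"))
}

#' @export
print.pre_dataset <- function(x, ...) {
  cat(sprintf("pre_dataset: %d ratios from %d label site(s): %s\n", nrow(x),
              length(unique(x$label_site)),
              paste(sort(unique(x$label_site)), collapse = ", ")))
  invisible(x)
}

#' Load a PRE intensity-ratio table
#'
#' Reads a delimited text file (comma- or whitespace-separated, autodetected)
#' with named columns `label_site`, `residue`, `ratio`, `error`.
#'
#' @param path file to read
#' @param n_residues optional chain length for validation
#' @return A [pre_dataset()].
#' @export
load_pre_table <- function(path, n_residues = NULL) {
  .assert(file.exists(path), "file not found: %s", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           strip.white = TRUE)
  pre_dataset(tab, n_residues = n_residues)
}

#' Write a PRE dataset as CSV
#' @param data a [pre_dataset()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_pre_table <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
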