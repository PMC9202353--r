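# Flat-table import/export of per-edge estimates.

.table_method_cols <- c(
  "BAR" = "BAR", "BARstar" = "BAR*", "J_FF" = "J(FF)", "J_RR" = "J(RR)",
  "Js_FR" = "J*(FR)", "Js_RF" = "J*(RF)", "G_FF" = "G(FF)", "G_RR" = "G(RR)")

#' Read a wide per-edge estimate table
#'
#' Reads a tab-separated table with one row per edge: columns `source`,
#' `target`, then per-method value columns (`BAR`, `BARstar`, `J_FF`,
#' `J_RR`, `Js_FR`, `Js_RF`, `G_FF`, `G_RR`, any subset) each with an
#' optional `_se` companion, plus the optional metadata columns `fs`,
#' `tanimoto`, `delta_volume`, `delta_charge`, `delta_n_rings`.  Missing
#' entries are `NA`.  Values are kcal/mol and are taken as final (any
#' finite-size correction already applied); the `fs` column is carried as
#' edge metadata.
#'
#' The package ships such a table for the 18 guest-pair transmutations of
#' the SAMPL9 WP6 host-guest network:
#' `system.file("extdata", "wp6_sampl9_rbfe.tsv", package = "nebar")`.
#'
#' @param path Path to the TSV file.
#' @return A long data frame with columns `source`, `target`, `method`,
#'   `value`, `stderr`, with the per-edge metadata attached as attribute
#'   `"edge_meta"` (a data frame).
#' @export
read_estimate_table <- function(path) {
  if (!file.exists(path)) stop("read_estimate_table: no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target") %in% names(df)))
  out <- list()
  for (col in intersect(names(.table_method_cols), names(df))) {
    se_col <- paste0(col, "_se")
    out[[col]] <- data.frame(
      source = df$source, target = df$target,
      method = .table_method_cols[[col]],
      value = as.numeric(df[[col]]),
      stderr = if (se_col %in% names(df)) as.numeric(df[[se_col]])
               else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("read_estimate_table: no method columns found")
  long <- do.call(rbind, out)
  long <- long[is.finite(long$value), , drop = FALSE]
  rownames(long) <- NULL
  meta_cols <- intersect(c("fs", "tanimoto", "delta_volume", "delta_charge",
                           "delta_n_rings"), names(df))
  attr(long, "edge_meta") <- df[c("source", "target", meta_cols)]
  long
}

#' Load a values-only network from a wide estimate table
#'
#' Convenience wrapper: [read_estimate_table()] followed by
#' [network_from_table()], attaching the finite-size corrections and
#' similarity metadata to the edges.
#'
#' @param path Path to the TSV file.
#' @return An `rbfe_network` (values-only).
#' @export
read_network <- function(path) {
  long <- read_estimate_table(path)
  meta <- attr(long, "edge_meta")
  edges <- lapply(seq_len(nrow(meta)), function(i) {
    g <- function(col) if (col %in% names(meta)) meta[[col]][i] else NA_real_
    edge_data(meta$source[i], meta$target[i],
              fs_correction = if (is.finite(g("fs"))) g("fs") else 0,
              similarity = similarity_record(
                tanimoto = g("tanimoto"),
                delta_volume = g("delta_volume"),
                delta_charge = g("delta_charge"),
                delta_n_rings = g("delta_n_rings")))
  })
  network_from_table(long, edges = edges)
}

#' Export per-edge estimates as a flat table
#'
#' Renders the network's estimates as a wide data frame with one row per
#' edge and one column pair (`value`, `_se`) per method, mirroring the
#' conventional results-table layout (pair, BAR, BAR*, fs correction,
#' unidirectional estimates).  Values in kcal/mol; `digits = NA` keeps
#' full precision, a number rounds for human-readable output.
#'
#' @param net An `rbfe_network`.
#' @param digits Round to this many decimals (default `NA`: no rounding).
#' @return A wide data frame.
#' @export
estimate_table <- function(net, digits = NA) {
  stopifnot(inherits(net, "rbfe_network"))
  pairs <- unique(net$estimates[c("source", "target")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- pairs$source[i]; t <- pairs$target[i]
    e <- net$edges[[.edge_key(s, t)]]
    row <- data.frame(source = s, target = t,
                      fs = if (!is.null(e)) e$fs_correction else NA_real_,
                      stringsAsFactors = FALSE)
    for (col in names(.table_method_cols)) {
      m <- .table_method_cols[[col]]
      v <- .lookup_edge_value(net, s, t, m)
      row[[col]] <- if (is.null(v)) NA_real_ else v$value
      row[[paste0(col, "_se")]] <- if (is.null(v)) NA_real_ else v$stderr
    }
    row
  })
  out <- do.call(rbind, rows)
  if (!is.na(digits)) {
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], round, digits = digits)
  }
  out
}
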