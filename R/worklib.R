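#' @importFrom stats sd var density cor lm coef rnorm runif qchisq setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Boltzmann constant in kcal mol^-1 K^-1
.kB <- 1.98720425864083e-3

#' Thermal beta 1/(kB T)
#'
#' @param temperature Temperature in kelvin.
#' @return `1 / (kB * temperature)` in mol/kcal, with
#'   kB = 1.98720425864083e-3 kcal mol^-1 K^-1.
#' @examples
#' thermal_beta(298.15)   # ~1.6878 mol/kcal
#' @export
thermal_beta <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1 / (.kB * temperature)
}

#' Nonequilibrium work sample for one alchemical leg and direction
#'
#' A `work_set` holds the work values (kcal/mol) accumulated by a swarm of
#' independent nonequilibrium alchemical trajectories, all driven in the same
#' direction (forward or reverse) on the same leg (bound or unbound) of the
#' dual-topology thermodynamic cycle.  A set produced by [convolve_work()]
#' carries `leg = "combined"`.
#'
#' Sign convention: a reverse set stores the work of the B-to-A process as
#' performed, not pre-negated; estimators handle all negations internally.
#'
#' @param values Numeric vector of work values, kcal/mol.  Must be non-empty
#'   and finite.
#' @param direction `"forward"` or `"reverse"`.
#' @param leg `"bound"`, `"unbound"` or `"combined"`.
#' @param temperature Temperature in kelvin (default 298.15).
#' @param label Free-text label.
#' @return An object of class `work_set`.
#' @examples
#' ws <- work_set(c(1.2, 0.8, 1.5), "forward", "bound")
#' mean(ws$values)
#' @export
work_set <- function(values, direction = c("forward", "reverse"),
                     leg = c("bound", "unbound", "combined"),
                     temperature = 298.15, label = "") {
  direction <- match.arg(direction)
  leg <- match.arg(leg)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("work_set: 'values' must be non-empty")
  if (!all(is.finite(values))) stop("work_set: all work values must be finite")
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("work_set: temperature must be a single positive number (kelvin)")
  structure(
    list(values = values, direction = direction, leg = leg,
         temperature = as.numeric(temperature), label = as.character(label)),
    class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("<work_set> %s/%s, n = %d, T = %.2f K%s\n",
              x$leg, x$direction, length(x$values), x$temperature,
              if (nzchar(x$label)) paste0(", ", x$label) else ""))
  cat(sprintf("  mean W = %.3f kcal/mol, sd = %.3f\n",
              mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' @export
length.work_set <- function(x) length(x$values)

# beta for a work_set
beta_of <- function(ws) thermal_beta(ws$temperature)

#' Read a plain-text work file
#'
#' One work value per trajectory.  Each non-comment line holds either a
#' single number (the work) or two numbers (trajectory index, work); the two
#' dialects may not be mixed in one file.  Lines starting with `#` are
#' comments.  Values are kcal/mol unless a header comment `# units kJ/mol`
#' is present, in which case they are divided by 4.184 on input.
#'
#' @param path Path to the work file.
#' @param direction,leg,temperature,label Passed to [work_set()].
#' @return A [work_set()] with the values in file order.
#' @seealso [write_work_file()]
#' @export
read_work_file <- function(path, direction, leg, temperature = 298.15,
                           label = basename(path)) {
  if (!file.exists(path)) stop("read_work_file: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  kj <- any(grepl("^\\s*#\\s*units\\s+kJ/mol\\s*$", lines, ignore.case = TRUE))
  vals <- numeric(0)
  ncols <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "\\s+")[[1]]
    if (!length(tok) %in% c(1L, 2L))
      stop("read_work_file: line ", i, ": expected 1 or 2 columns, got ",
           length(tok))
    if (is.na(ncols)) ncols <- length(tok)
    if (length(tok) != ncols)
      stop("read_work_file: line ", i,
           ": mixed 1-column and 2-column lines are not allowed")
    w <- suppressWarnings(as.numeric(tok[length(tok)]))
    if (is.na(w))
      stop("read_work_file: line ", i, ": non-numeric token '",
           tok[length(tok)], "'")
    if (ncols == 2L && is.na(suppressWarnings(as.numeric(tok[1L]))))
      stop("read_work_file: line ", i, ": non-numeric token '", tok[1L], "'")
    vals <- c(vals, w)
  }
  if (length(vals) == 0L) stop("read_work_file: no work values in ", path)
  if (kj) vals <- vals / 4.184
  work_set(vals, direction = direction, leg = leg,
           temperature = temperature, label = label)
}

#' Write a work set to a plain-text work file
#'
#' Writes one value per line at full double precision (kcal/mol), suitable
#' for round-tripping through [read_work_file()].
#'
#' @param ws A [work_set()].
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `# `).
#' @return `path`, invisibly.
#' @export
write_work_file <- function(ws, path, header = NULL) {
  stopifnot(inherits(ws, "work_set"))
  out <- character(0)
  if (!is.null(header)) out <- paste0("# ", header)
  out <- c(out, sprintf("%.17g", ws$values))
  writeLines(out, path)
  invisible(path)
}

#' Chemical-dissimilarity metadata for a compound pair
#'
#' All fields are optional; the record may be empty.  The deltas are signed
#' for the A-to-B sense of the owning edge.
#'
#' @param tanimoto Tanimoto coefficient of the two fingerprints, in `[0, 1]`.
#' @param delta_volume Volume change, cubic Angstrom.
#' @param delta_charge Net-charge change, electron units.
#' @param delta_n_rings Change in the number of rings.
#' @param rel_charge_change,rel_volume_change Optional user-supplied relative
#'   (normalised) charge and volume change metrics.
#' @return An object of class `similarity_record`.
#' @export
similarity_record <- function(tanimoto = NA_real_, delta_volume = NA_real_,
                              delta_charge = NA_real_,
                              delta_n_rings = NA_real_,
                              rel_charge_change = NA_real_,
                              rel_volume_change = NA_real_) {
  if (!is.na(tanimoto) && (tanimoto < 0 || tanimoto > 1))
    stop("similarity_record: tanimoto must lie in [0, 1]")
  structure(
    list(tanimoto = as.numeric(tanimoto),
         delta_volume = as.numeric(delta_volume),
         delta_charge = as.numeric(delta_charge),
         delta_n_rings = as.numeric(delta_n_rings),
         rel_charge_change = as.numeric(rel_charge_change),
         rel_volume_change = as.numeric(rel_volume_change)),
    class = "similarity_record")
}

.work_keys <- c("bound_forward", "bound_reverse",
                "unbound_forward", "unbound_reverse")

#' Alchemical edge: one compound pair with its work samples
#'
#' An edge represents the transmutation of `source` into `target` and can
#' carry up to four work sets, one per (leg, direction) combination, keyed
#' `bound_forward`, `bound_reverse`, `unbound_forward`, `unbound_reverse`.
#' A bidirectional edge has all four; a unidirectional edge needs at least
#' the bound and unbound sets of one direction.
#'
#' @param source,target Compound identifiers; must differ.
#' @param works Named list of [work_set()] objects keyed as above.
#' @param fs_correction Finite-size correction (kcal/mol) applied a
#'   posteriori to the edge RBFE when the transmutation changes the net
#'   charge; supplied per edge, default 0.
#' @param similarity A [similarity_record()].
#' @return An object of class `edge_data`.
#' @export
edge_data <- function(source, target, works = list(), fs_correction = 0,
                      similarity = similarity_record()) {
  if (identical(source, target)) stop("edge_data: source and target must differ")
  if (length(works)) {
    bad <- setdiff(names(works), .work_keys)
    if (length(bad)) stop("edge_data: unknown work keys: ",
                          paste(bad, collapse = ", "))
    for (k in names(works)) {
      ws <- works[[k]]
      if (!inherits(ws, "work_set")) stop("edge_data: works$", k,
                                          " is not a work_set")
      parts <- strsplit(k, "_")[[1]]
      if (ws$leg != parts[1] || ws$direction != parts[2])
        stop("edge_data: works$", k, " is tagged ", ws$leg, "/", ws$direction)
    }
    temps <- vapply(works, function(w) w$temperature, numeric(1))
    if (diff(range(temps)) > 1e-9)
      stop("edge_data: temperature mismatch across work sets (",
           paste(format(temps), collapse = ", "), ")")
  }
  structure(
    list(source = as.character(source), target = as.character(target),
         works = works, fs_correction = as.numeric(fs_correction),
         similarity = similarity),
    class = "edge_data")
}

#' @export
print.edge_data <- function(x, ...) {
  cat(sprintf("<edge_data> %s -> %s, %d work set(s), fs = %.2f kcal/mol\n",
              x$source, x$target, length(x$works), x$fs_correction))
  invisible(x)
}

#' Reverse the declared sense of an edge
#'
#' Swaps source and target, exchanges forward and reverse work sets within
#' each leg, negates the finite-size correction and the signed similarity
#' deltas (volume, charge, ring count); the Tanimoto coefficient is
#' symmetric and kept as is.  `reverse_edge` is an involution.
#'
#' @param edge An [edge_data()].
#' @return The edge with the opposite declared sense.
#' @export
reverse_edge <- function(edge) {
  stopifnot(inherits(edge, "edge_data"))
  swap <- c(bound_forward = "bound_reverse", bound_reverse = "bound_forward",
            unbound_forward = "unbound_reverse",
            unbound_reverse = "unbound_forward")
  works <- list()
  for (k in names(edge$works)) {
    ws <- edge$works[[k]]
    ws$direction <- if (ws$direction == "forward") "reverse" else "forward"
    works[[swap[[k]]]] <- ws
  }
  works <- works[intersect(.work_keys, names(works))]  # canonical order
  sim <- edge$similarity
  sim$delta_volume <- -sim$delta_volume
  sim$delta_charge <- -sim$delta_charge
  sim$delta_n_rings <- -sim$delta_n_rings
  sim$rel_charge_change <- -sim$rel_charge_change
  sim$rel_volume_change <- -sim$rel_volume_change
  edge_data(edge$target, edge$source, works = works,
            fs_correction = -edge$fs_correction, similarity = sim)
}

#' Read an RBFE edge manifest
#'
#' The manifest is a YAML document describing one network: a top-level
#' optional `temperature` (kelvin, default 298.15) and an `edges` list.
#' Each edge entry carries `source`, `target`, a `files` mapping with any of
#' the keys `bound_forward`, `bound_reverse`, `unbound_forward`,
#' `unbound_reverse` (paths resolved relative to the manifest), and the
#' optional scalars `fs_correction` (default 0), `temperature`, `tanimoto`,
#' `delta_volume`, `delta_charge`, `delta_n_rings`.
#'
#' @param path Path to the manifest file.
#' @return A list of [edge_data()] objects.
#' @export
read_edge_manifest <- function(path) {
  if (!file.exists(path)) stop("read_edge_manifest: no such file: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$edges) || !length(doc$edges))
    stop("read_edge_manifest: manifest has no edges")
  base <- dirname(normalizePath(path))
  t_default <- if (!is.null(doc$temperature)) doc$temperature else 298.15
  seen <- character(0)
  out <- vector("list", length(doc$edges))
  for (i in seq_along(doc$edges)) {
    e <- doc$edges[[i]]
    if (is.null(e$source) || is.null(e$target))
      stop("read_edge_manifest: edge ", i, " lacks source/target")
    key <- paste(e$source, e$target, sep = "|")
    if (key %in% seen)
      stop("read_edge_manifest: duplicate pair ", e$source, " -> ", e$target)
    seen <- c(seen, key)
    temp <- if (!is.null(e$temperature)) e$temperature else t_default
    works <- list()
    for (k in intersect(names(e$files), .work_keys)) {
      fp <- e$files[[k]]
      if (!file.exists(fp)) fp <- file.path(base, e$files[[k]])
      if (!file.exists(fp))
        stop("read_edge_manifest: work file not found: ", e$files[[k]])
      parts <- strsplit(k, "_")[[1]]
      works[[k]] <- read_work_file(fp, direction = parts[2], leg = parts[1],
                                   temperature = temp)
    }
    bad <- setdiff(names(e$files), .work_keys)
    if (length(bad))
      stop("read_edge_manifest: edge ", i, ": unknown file keys: ",
           paste(bad, collapse = ", "))
    sim <- similarity_record(
      tanimoto = if (is.null(e$tanimoto)) NA_real_ else e$tanimoto,
      delta_volume = if (is.null(e$delta_volume)) NA_real_ else e$delta_volume,
      delta_charge = if (is.null(e$delta_charge)) NA_real_ else e$delta_charge,
      delta_n_rings = if (is.null(e$delta_n_rings)) NA_real_ else e$delta_n_rings)
    out[[i]] <- edge_data(e$source, e$target, works = works,
                          fs_correction = if (is.null(e$fs_correction)) 0
                                          else e$fs_correction,
                          similarity = sim)
  }
  out
}
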