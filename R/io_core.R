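#' Transform specification
#'
#' Describes the intensity transform used for gating. Only the inverse
#' hyperbolic sine (`asinh`) is supported: it is linear near zero and
#' logarithmic for bright signals, which suits conventional-cytometer
#' fluorescence ranges. The default cofactor of 150 places the transition
#' around typical autofluorescence levels.
#'
#' @param kind Transform kind; only `"asinh"` is available.
#' @param cofactor Positive divisor applied before `asinh`.
#' @return An object of class `TransformSpec`.
#' @export
transform_spec <- function(kind = "asinh", cofactor = 150) {
  kind <- match.arg(kind, "asinh")
  if (!is.numeric(cofactor) || length(cofactor) != 1L || !is.finite(cofactor) ||
      cofactor <= 0) {
    stop("cofactor must be a single positive number", call. = FALSE)
  }
  structure(list(kind = kind, cofactor = as.numeric(cofactor)),
            class = "TransformSpec")
}

#' Panel configuration
#'
#' Declares which markers an analysis requires and how detector or vendor
#' names map onto canonical marker names (e.g. `"podoplanin"` -> `"pdpn"`).
#'
#' @param required_markers Character vector of marker names that must be
#'   present (after alias resolution) in any event table read with this panel.
#' @param marker_aliases Named character vector mapping alias -> canonical
#'   marker name.
#' @return An object of class `PanelConfig`.
#' @export
panel_config <- function(required_markers = character(),
                         marker_aliases = c(podoplanin = "pdpn")) {
  required_markers <- as.character(required_markers)
  if (length(marker_aliases)) {
    if (is.null(names(marker_aliases)) || any(!nzchar(names(marker_aliases)))) {
      stop("marker_aliases must be a named character vector", call. = FALSE)
    }
    marker_aliases <- vapply(marker_aliases, as.character, character(1))
  } else {
    marker_aliases <- c(character(0))
  }
  structure(list(required_markers = required_markers,
                 marker_aliases = marker_aliases),
            class = "PanelConfig")
}

#' Default thymic stromal panel
#'
#' The 13-marker panel used by the thymic stromal gating scheme: EpCAM and
#' pdpn to capture all thymic epithelial cells, CD49f/CD200 to split cTEC from
#' mTEC, CD31 for (lymphatic) endothelium, HLA-DR/CD11c/CD11b for myeloid
#' antigen-presenting cells, CD3/CD1a/CD4/CD8 for thymocyte subsets, and CD45
#' for the hematopoietic/stromal split in accessory gates.
#'
#' @return A `PanelConfig`.
#' @export
default_thymic_panel <- function() {
  panel_config(
    required_markers = c("CD45", "EpCAM", "pdpn", "CD49f", "CD200", "CD31",
                         "HLA-DR", "CD11c", "CD11b", "CD3", "CD1a",
                         "CD4", "CD8"),
    marker_aliases = c(podoplanin = "pdpn", Podoplanin = "pdpn",
                       PDPN = "pdpn", "NC-08" = "pdpn",
                       "EPCAM" = "EpCAM", "CD326" = "EpCAM",
                       "ITGA6" = "CD49f", "HLADR" = "HLA-DR")
  )
}

#' Resolve marker names through panel aliases
#'
#' Resolution is idempotent: canonical names map to themselves.
#'
#' @param markers Character vector of marker names.
#' @param panel A `PanelConfig` (or `NULL` for no-op).
#' @return Character vector of canonical marker names.
#' @export
resolve_markers <- function(markers, panel = NULL) {
  if (is.null(panel)) return(markers)
  stopifnot(inherits(panel, "PanelConfig"))
  ali <- panel$marker_aliases
  hit <- markers %in% names(ali)
  markers[hit] <- unname(ali[markers[hit]])
  markers
}

#' Construct an event table
#'
#' The unit every gate operates on: an events x channels matrix of
#' fluorescence intensities plus channel metadata and the scale state
#' (raw instrument scale or asinh-transformed).
#'
#' @param events Numeric matrix, events in rows, channels in columns.
#' @param markers Marker name per channel; defaults to `colnames(events)`.
#' @param sample_id Sample identifier.
#' @param detectors Optional detector name per channel.
#' @param scale_state `"raw"` or `"transformed"`.
#' @param transform A `TransformSpec`, required iff `scale_state` is
#'   `"transformed"`.
#' @return An object of class `EventTable`.
#' @export
event_table <- function(events, markers = colnames(events),
                        sample_id = "sample", detectors = NULL,
                        scale_state = c("raw", "transformed"),
                        transform = NULL) {
  scale_state <- match.arg(scale_state)
  events <- as.matrix(events)
  storage.mode(events) <- "double"
  if (is.null(markers)) stop("markers must be supplied", call. = FALSE)
  markers <- as.character(markers)
  if (length(markers) != ncol(events)) {
    stop("one marker name per channel is required", call. = FALSE)
  }
  if (anyDuplicated(markers)) {
    stop("marker names must be unique within an event table", call. = FALSE)
  }
  if (any(!nzchar(markers))) stop("marker names must be non-empty", call. = FALSE)
  if (anyNA(events)) stop("event intensities must not contain missing values",
                          call. = FALSE)
  if (scale_state == "transformed" && is.null(transform)) {
    stop("a transformed table must carry its TransformSpec", call. = FALSE)
  }
  if (scale_state == "raw" && !is.null(transform)) {
    stop("a raw table must not carry a TransformSpec", call. = FALSE)
  }
  colnames(events) <- markers
  channels <- data.frame(marker = markers,
                         detector = if (is.null(detectors)) NA_character_
                                    else as.character(detectors),
                         stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, events = events, channels = channels,
                 scale_state = scale_state, transform = transform),
            class = "EventTable")
}

#' @export
print.EventTable <- function(x, ...) {
  cat(sprintf("EventTable '%s': %d events x %d channels [%s]\n",
              x$sample_id, nrow(x$events), ncol(x$events), x$scale_state))
  cat("  markers:", paste(x$channels$marker, collapse = ", "), "\n")
  invisible(x)
}

#' Number of events in an event table
#' @param table An `EventTable`.
#' @return Integer event count.
#' @export
n_events <- function(table) nrow(table$events)

#' Marker names of an event table
#' @param table An `EventTable`.
#' @return Character vector of markers, in channel order.
#' @export
markers <- function(table) table$channels$marker

# clip negatives in place, warning with the affected count
clip_negatives <- function(events) {
  nneg <- sum(events < 0)
  if (nneg > 0) {
    warning(sprintf("%d negative intensit%s clipped to 0 on read",
                    nneg, if (nneg == 1) "y" else "ies"), call. = FALSE)
    events[events < 0] <- 0
  }
  events
}

check_required <- function(mk, panel) {
  if (is.null(panel)) return(invisible(NULL))
  miss <- setdiff(panel$required_markers, mk)
  if (length(miss)) {
    stop(sprintf("panel error: missing required marker(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

#' Read cytometry events from file
#'
#' Reads FCS 3.1 (primary data segment; spillover matrices are ignored) or
#' CSV (comma-separated, a single header row of marker names, no index
#' column). Marker names are resolved through the panel's aliases and the
#' panel's required markers are checked. Negative intensities -- possible
#' after instrument baseline subtraction -- are clipped to 0 with a warning,
#' since downstream ratio statistics assume non-negative signals.
#'
#' @param path Input file path.
#' @param format `"fcs"` or `"csv"`.
#' @param panel Optional `PanelConfig` for alias resolution and requirement
#'   checks.
#' @return An `EventTable` (scale state as recorded in the file; CSV/FCS files
#'   written by [write_events()] round-trip their transform metadata).
#' @export
read_events <- function(path, format = c("csv", "fcs"), panel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- switch(format, csv = read_events_csv(path), fcs = read_events_fcs(path))
  tab$channels$marker <- resolve_markers(tab$channels$marker, panel)
  if (anyDuplicated(tab$channels$marker)) {
    stop("alias resolution produced duplicate marker names", call. = FALSE)
  }
  colnames(tab$events) <- tab$channels$marker
  check_required(tab$channels$marker, panel)
  if (tab$scale_state == "raw") tab$events <- clip_negatives(tab$events)
  tab
}

#' Write cytometry events to file
#'
#' Writes an [event_table()] as FCS 3.1 or CSV. A transformed table records
#' its transform kind and cofactor in the file metadata (FCS TEXT keywords, or
#' a leading `#` comment line in CSV) so that [read_events()] reproduces the
#' scale state.
#'
#' @param table An `EventTable` with at least one channel.
#' @param path Output file path.
#' @param format `"fcs"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "EventTable"))
  if (ncol(table$events) < 1L) {
    stop("cannot write a table with no channels", call. = FALSE)
  }
  switch(format,
         csv = write_events_csv(table, path),
         fcs = write_events_fcs(table, path))
  invisible(path)
}

read_events_csv <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- NULL
  if (startsWith(first, "#")) meta <- parse_scale_comment(first)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  ev <- as.matrix(df)
  storage.mode(ev) <- "double"
  if (nrow(ev) > 0 && anyNA(ev)) {
    stop(sprintf("format error: non-numeric or missing values in %s", path),
         call. = FALSE)
  }
  if (is.null(meta)) {
    event_table(ev, markers = colnames(df),
                sample_id = sub("\\.[^.]*$", "", basename(path)))
  } else {
    event_table(ev, markers = colnames(df),
                sample_id = sub("\\.[^.]*$", "", basename(path)),
                scale_state = "transformed",
                transform = transform_spec(meta$kind, meta$cofactor))
  }
}

parse_scale_comment <- function(line) {
  if (!grepl("scale_state=transformed", line, fixed = TRUE)) return(NULL)
  kind <- sub(".*transform=([a-z]+).*", "\\1", line)
  cof <- as.numeric(sub(".*cofactor=([0-9.eE+-]+).*", "\\1", line))
  list(kind = kind, cofactor = cof)
}

write_events_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (table$scale_state == "transformed") {
    writeLines(sprintf("# scale_state=transformed transform=%s cofactor=%g",
                       table$transform$kind, table$transform$cofactor), con)
  }
  utils::write.table(table$events, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
}

#' Apply the intensity transform
#'
#' Replaces every intensity x by `asinh(x / cofactor)`. The input table is
#' left unmodified (copy semantics). Rank order within each channel is
#' preserved exactly since asinh is strictly increasing.
#'
#' @param table A raw-scale `EventTable`.
#' @param spec A `TransformSpec`.
#' @return A transformed `EventTable`.
#' @export
transform_events <- function(table, spec = transform_spec()) {
  stopifnot(inherits(table, "EventTable"), inherits(spec, "TransformSpec"))
  if (table$scale_state != "raw") {
    stop("state error: table is already transformed", call. = FALSE)
  }
  out <- table
  out$events <- asinh(table$events / spec$cofactor)
  out$scale_state <- "transformed"
  out$transform <- spec
  out
}

#' Invert the intensity transform
#'
#' Recovers raw-scale intensities via `sinh(y) * cofactor`.
#'
#' @param table A transformed `EventTable`.
#' @return A raw-scale `EventTable`.
#' @export
inverse_transform_events <- function(table) {
  stopifnot(inherits(table, "EventTable"))
  if (table$scale_state != "transformed") {
    stop("state error: table is not transformed", call. = FALSE)
  }
  out <- table
  out$events <- sinh(table$events) * table$transform$cofactor
  out$scale_state <- "raw"
  out$transform <- NULL
  out
}

#' Read a panel or transform configuration from a YAML file
#'
#' @param path Path to a YAML file with optional top-level keys
#'   `required_markers`, `marker_aliases`, `transform` (with `kind`,
#'   `cofactor`).
#' @return A list with elements `panel` (`PanelConfig`) and `transform`
#'   (`TransformSpec` or `NULL`).
#' @export
read_panel_config <- function(path) {
  y <- yaml::read_yaml(path)
  ali <- unlist(y$marker_aliases %||% list())
  pan <- panel_config(required_markers = y$required_markers %||% character(),
                      marker_aliases = if (length(ali)) ali else c(podoplanin = "pdpn"))
  tr <- NULL
  if (!is.null(y$transform)) {
    tr <- transform_spec(y$transform$kind %||% "asinh",
                         y$transform$cofactor %||% 150)
  }
  list(panel = pan, transform = tr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
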