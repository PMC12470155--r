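# Dinucleotide structural-property models: 16 step values per model, applied
# to binned dinucleotide counts to produce property tracks.

#' Construct a dinucleotide property model
#'
#' @param id integer model identifier.
#' @param name property name, e.g. `"Roll"`.
#' @param values named numeric(16) of step values (names AA..TT, any order).
#' @param units optional unit string.
#' @param source optional provenance string.
#' @return A `property_model` object.
#' @export
property_model <- function(id, name, values, units = NA_character_,
                           source = NA_character_) {
  stopifnot(length(values) == 16L, !is.null(names(values)))
  if (!setequal(names(values), .DINUCS)) {
    stop("model must provide a value for each of the 16 dinucleotides")
  }
  values <- values[.DINUCS]
  if (any(!is.finite(values))) stop("model values must be finite")
  structure(list(id = as.integer(id), name = as.character(name),
                 values = values, units = units, source = source),
            class = "property_model")
}

#' @export
print.property_model <- function(x, ...) {
  cat("<property_model> ", model_label(x), if (!is.na(x$units)) paste0(" [", x$units, "]"),
      "\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' Display label of a model, e.g. "Roll (94)"
#' @param model a `property_model`.
#' @export
model_label <- function(model) sprintf("%s (%d)", model$name, model$id)

#' Load a table of dinucleotide property models
#'
#' The table has one model per row with columns `id`, `name`, the 16
#' dinucleotide columns `AA` ... `TT`, and optionally `units` and `source`.
#' Without a `path`, the bundled fixture table of representative models is
#' loaded (synthetic fixture values with literature-typical magnitudes; tests
#' rely only on model invariants, never on these magnitudes).
#'
#' @param path TSV/CSV file, or `NULL` for the bundled table.
#' @return Named list of [property_model()]s, keyed by label ("Roll (94)").
#' @export
load_model_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dinucleotide_property_models.tsv",
                                package = "dinuscape", mustWork = TRUE)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "name", .DINUCS), names(tab))
  if (length(miss) > 0L) {
    stop("model table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) stop("duplicate model ids in table")
  models <- lapply(seq_len(nrow(tab)), function(i) {
    vals <- as.numeric(tab[i, .DINUCS])
    if (any(is.na(vals))) stop("model ", tab$id[i], " has missing values")
    property_model(tab$id[i], tab$name[i], stats::setNames(vals, .DINUCS),
                   units = if ("units" %in% names(tab)) tab$units[i] else NA,
                   source = if ("source" %in% names(tab)) tab$source[i] else NA)
  })
  stats::setNames(models, vapply(models, model_label, character(1L)))
}

#' Apply a property model to binned dinucleotide counts
#'
#' Per bin, the `sum` mode gives `sum(m_XY * n_XY)`; the `mean` mode (default)
#' divides by the bin's total dinucleotide count, which makes bins with
#' different valid lengths comparable. Invalid bins (valid fraction < 0.5, or
#' no dinucleotides at all under `mean`) propagate as `NA`.
#'
#' @param model a [property_model()].
#' @param dinucs a `dinuc_tracks` object from [count_dinucleotides()] (or an
#'   expectation set from [expected_dinucleotides()]).
#' @param mode `"mean"` or `"sum"`.
#' @return A [binned_track()] of property values, with the model label and
#'   mode attached as attributes `"model"` and `"mode"`.
#' @export
apply_model <- function(model, dinucs, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "property_model"))
  m <- model$values[.DINUCS]
  values <- lapply(names(dinucs$di), function(ch) {
    di <- dinucs$di[[ch]][, .DINUCS, drop = FALSE]
    v <- as.numeric(di %*% m)
    if (mode == "mean") {
      tot <- rowSums(di)
      v <- ifelse(tot > 0, v / tot, NA_real_)
    }
    v[dinucs$valid[[ch]] < 0.5] <- NA_real_
    v
  })
  names(values) <- names(dinucs$di)
  out <- binned_track(values, dinucs$valid, dinucs$resolution, dinucs$lengths)
  attr(out, "model") <- model_label(model)
  attr(out, "mode") <- mode
  out
}
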