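#' The default COSTAS scoring table
#'
#' The score is driven by a band table rather than hard-coded branches so
#' that a multicenter recalibration can ship a revised table as
#' configuration. Each row is one band of one parameter: a real interval
#' `[lower, upper]` whose endpoints are included or excluded according to
#' `lower_closed` / `upper_closed`, the points awarded inside it, a category
#' label, and an optional transparency flag. Printed band edges are treated
#' as edges of half-open real intervals (the underlying quantities are
#' continuous), with the gaps between printed bands closed as follows:
#'
#' * P/F ratio exactly 100 mmHg falls in the severe band (3 points) --
#'   conservative toward severity.
#' * Noradrenaline doses between 0.5 and 0.6 mg/h and between 1.9 and
#'   2 mg/h fall in the next-higher band.
#' * Values better than the best printed band (eGFR >= 60 mL/min,
#'   P/F > 300 mmHg, PEEP < 5 cm H2O, BMI < 18.5) score 0, some with a
#'   flag so reports stay transparent.
#' * PEEP above the printed 20 cm H2O ceiling still scores 3, flagged
#'   `peep_above_band`.
#'
#' Boolean parameters (smoking, adjudicated IAA) are banded on their 0/1
#' numeric encoding. The AI-risk bands 51-74% are read on the probability
#' scale as the open interval (0.50, 0.75) so that every probability in
#' [0, 1] maps to exactly one band.
#'
#' @return A data frame of class `costas_table` with columns `parameter`,
#'   `lower`, `upper`, `lower_closed`, `upper_closed`, `points`, `label`,
#'   `flag`, and a `version` attribute.
#' @seealso [read_scoring_table()], [write_scoring_table()], [total_score()]
#' @export
costas_table <- function() {
  b <- function(parameter, lower, upper, lc, uc, points, label, flag = NA_character_) {
    data.frame(parameter = parameter, lower = lower, upper = upper,
               lower_closed = lc, upper_closed = uc, points = as.integer(points),
               label = label, flag = flag, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    b("age",           0, 65,   TRUE,  FALSE, 0, "<65 y"),
    b("age",          65, Inf,  TRUE,  FALSE, 1, ">=65 y"),

    b("smoking",       0, 1,    TRUE,  FALSE, 0, "non-smoker"),
    b("smoking",       1, Inf,  TRUE,  FALSE, 1, "smoker"),

    b("iaa",           0, 50,   TRUE,  FALSE, 0, "stenosis <50%"),
    b("iaa",          50, Inf,  TRUE,  FALSE, 1, "stenosis >=50%"),

    b("bmi",           0, 18.5, FALSE, FALSE, 0, "underweight", "underweight_unspecified"),
    b("bmi",        18.5, 25,   TRUE,  FALSE, 0, "normal weight"),
    b("bmi",          25, 30,   TRUE,  FALSE, 1, "overweight"),
    b("bmi",          30, Inf,  TRUE,  FALSE, 2, "obesity"),

    b("gfr",           0, 30,   TRUE,  FALSE, 2, "high risk"),
    b("gfr",          30, 45,   TRUE,  FALSE, 1, "moderate risk"),
    b("gfr",          45, 60,   TRUE,  FALSE, 0, "low risk"),
    b("gfr",          60, Inf,  TRUE,  FALSE, 0, "no risk", "above_kdoqi_bands"),

    b("pf_ratio",      0, 100,  FALSE, TRUE,  3, "severe"),
    b("pf_ratio",    100, 200,  FALSE, TRUE,  2, "moderate"),
    b("pf_ratio",    200, 300,  FALSE, TRUE,  1, "mild"),
    b("pf_ratio",    300, Inf,  FALSE, FALSE, 0, "no impairment"),

    b("peep",          0, 5,    TRUE,  FALSE, 0, "minimal"),
    b("peep",          5, 10,   TRUE,  FALSE, 1, "mild"),
    b("peep",         10, 15,   TRUE,  FALSE, 2, "moderate"),
    b("peep",         15, 20,   TRUE,  TRUE,  3, "severe"),
    b("peep",         20, Inf,  FALSE, FALSE, 3, "severe", "peep_above_band"),

    b("noradrenaline", 0, 0,    TRUE,  TRUE,  0, "none"),
    b("noradrenaline", 0, 0.5,  FALSE, TRUE,  1, "low risk"),
    b("noradrenaline", 0.5, 2,  FALSE, FALSE, 2, "moderate risk"),
    b("noradrenaline", 2, Inf,  TRUE,  FALSE, 3, "high risk"),

    b("ai_risk",       0, 0.5,  TRUE,  TRUE,  0, "low risk"),
    b("ai_risk",     0.5, 0.75, FALSE, FALSE, 1, "moderate risk"),
    b("ai_risk",    0.75, 1,    TRUE,  TRUE,  2, "high risk")
  )
  attr(tab, "version") <- "costas-1.0"
  class(tab) <- c("costas_table", "data.frame")
  validate_scoring_table(tab)
}

#' The nine scored parameters, in report order
#' @return Character vector of parameter names.
#' @export
costas_parameters <- function() {
  c("age", "smoking", "iaa", "bmi", "gfr",
    "pf_ratio", "peep", "noradrenaline", "ai_risk")
}

#' Validate a scoring table
#'
#' Checks that, within each parameter, bands are ordered, non-overlapping
#' and gap-free (adjacent bands share an edge with complementary closure),
#' that the table covers every scored parameter up to `Inf`, that points
#' are integers in 0-3, and that the per-parameter maxima sum to 18.
#'
#' @param tab A scoring-table data frame as returned by [costas_table()].
#' @return The table, invisibly classed as `costas_table`.
#' @export
validate_scoring_table <- function(tab) {
  need <- c("parameter", "lower", "upper", "lower_closed", "upper_closed",
            "points", "label", "flag")
  if (!all(need %in% names(tab)))
    abort_validation(paste("scoring table is missing columns:",
                           paste(setdiff(need, names(tab)), collapse = ", ")))
  if (!setequal(unique(tab$parameter), costas_parameters()))
    abort_validation("scoring table must cover exactly the nine scored parameters")
  if (any(tab$points < 0L | tab$points > 3L))
    abort_validation("band points must lie in 0..3")
  for (p in costas_parameters()) {
    bands <- tab[tab$parameter == p, , drop = FALSE]
    bands <- bands[order(bands$lower, bands$upper), , drop = FALSE]
    if (any(bands$upper < bands$lower))
      abort_validation(sprintf("parameter %s has a band with upper < lower", p))
    if (nrow(bands) > 1L) {
      for (i in seq_len(nrow(bands) - 1L)) {
        if (bands$upper[i] != bands$lower[i + 1L] ||
            !xor(bands$upper_closed[i], bands$lower_closed[i + 1L]))
          abort_validation(sprintf(
            "parameter %s: bands %d and %d overlap or leave a gap", p, i, i + 1L))
      }
    }
    top <- if (p == "ai_risk") 1 else Inf  # probabilities live in [0, 1]
    last <- nrow(bands)
    covered <- bands$upper[last] > top ||
      (bands$upper[last] == top && (is.infinite(top) || bands$upper_closed[last]))
    if (!covered)
      abort_validation(sprintf(
        "parameter %s: bands must cover the full range up to %s", p, top))
  }
  maxima <- parameter_maxima(tab)
  if (sum(maxima) != 18L)
    abort_validation(sprintf(
      "per-parameter maxima must sum to 18, got %d", sum(maxima)))
  class(tab) <- unique(c("costas_table", class(tab)))
  invisible(tab)
}

#' Maximum attainable points per parameter
#'
#' @param tab A scoring table; defaults to the shipped one.
#' @return Named integer vector (one entry per parameter, report order).
#' @export
parameter_maxima <- function(tab = costas_table()) {
  vapply(costas_parameters(), function(p)
    max(tab$points[tab$parameter == p]), integer(1))
}

# Vectorised band lookup: returns the matching band row index per value.
match_band <- function(tab, parameter, values) {
  bands <- tab[tab$parameter == parameter, , drop = FALSE]
  idx <- rep(NA_integer_, length(values))
  for (i in seq_len(nrow(bands))) {
    lo <- if (bands$lower_closed[i]) values >= bands$lower[i] else values > bands$lower[i]
    hi <- if (bands$upper_closed[i]) values <= bands$upper[i] else values < bands$upper[i]
    hit <- lo & hi & is.na(idx)
    idx[hit] <- i
  }
  if (anyNA(idx[!is.na(values)]))
    abort_validation(sprintf(
      "value(s) outside every %s band: %s", parameter,
      paste(utils::head(values[is.na(idx) & !is.na(values)], 3), collapse = ", ")))
  bands[idx, , drop = FALSE]
}

#' Read / write a scoring table as YAML
#'
#' The YAML layout carries a `version` tag and one mapping per band, so a
#' revised multicenter table can be supplied with `--table` on the command
#' line without touching code. `Inf` is written as the string `.inf`.
#'
#' @param path File path.
#' @param tab A validated scoring table.
#' @return `read_scoring_table()` returns a validated `costas_table`;
#'   `write_scoring_table()` returns `path` invisibly.
#' @export
read_scoring_table <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("scoring table not found: %s", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$bands)) abort_io("scoring-table YAML must contain a 'bands' list")
  rows <- lapply(doc$bands, function(bnd) {
    data.frame(parameter = bnd$parameter,
               lower = as.numeric(bnd$lower), upper = as.numeric(bnd$upper),
               lower_closed = isTRUE(bnd$lower_closed),
               upper_closed = isTRUE(bnd$upper_closed),
               points = as.integer(bnd$points), label = bnd$label,
               flag = if (is.null(bnd$flag)) NA_character_ else bnd$flag,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  attr(tab, "version") <- if (is.null(doc$version)) "unversioned" else doc$version
  validate_scoring_table(tab)
  tab
}

#' @rdname read_scoring_table
#' @export
write_scoring_table <- function(tab, path) {
  validate_scoring_table(tab)
  bands <- lapply(seq_len(nrow(tab)), function(i) {
    bnd <- list(parameter = tab$parameter[i],
                lower = tab$lower[i], upper = tab$upper[i],
                lower_closed = tab$lower_closed[i],
                upper_closed = tab$upper_closed[i],
                points = tab$points[i], label = tab$label[i])
    if (!is.na(tab$flag[i])) bnd$flag <- tab$flag[i]
    bnd
  })
  yaml::write_yaml(list(version = attr(tab, "version"), bands = bands), path)
  invisible(path)
}
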