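#' PANSS item names
#'
#' The 30 items of the Positive and Negative Syndrome Scale: positive P1-P7,
#' negative N1-N7, general psychopathology G1-G16, each rated 1-7.
#' @return character vector of length 30.
#' @export
panss_item_names <- function() {
  c(sprintf("P%d", 1:7), sprintf("N%d", 1:7), sprintf("G%d", 1:16))
}

# Five-factor item lists (consensus factor model of the PANSS).
panss_factor_items <- function() {
  list(
    positive   = c("P1", "P3", "P5", "P6"),
    negative   = c("N1", "N2", "N3", "N4", "N6", "G7", "G16"),
    cognitive  = c("P2", "N5", "G9", "G10", "G11", "G13", "G15"),
    excitement = c("P4", "P7", "G8", "G12", "G14"),
    depression = c("G2", "G3", "G4", "G6")
  )
}

validate_panss <- function(items) {
  need <- panss_item_names()
  if (!all(need %in% names(items))) {
    stop("missing PANSS item(s): ",
         paste(setdiff(need, names(items)), collapse = ", "))
  }
  v <- items[need]
  if (any(is.na(v)) || any(v < 1 | v > 7) || any(v != round(v))) {
    stop("PANSS items must be integers in 1..7")
  }
  v
}

#' Score PANSS subscales and five-factor model
#'
#' Computes the standard subscale sums (positive P1-P7, negative N1-N7,
#' general G1-G16, total) and the five-factor sums: positive (P1, P3, P5,
#' P6), negative (N1, N2, N3, N4, N6, G7, G16), cognitive/disorganization
#' (P2, N5, G9, G10, G11, G13, G15), excitement (P4, P7, G8, G12, G14) and
#' depression/anxiety (G2, G3, G4, G6).
#'
#' @param items named integer vector (or one-row data.frame) with the 30
#'   PANSS items, each in 1..7.
#' @return named list of integer scores: `positive`, `negative`, `cognitive`,
#'   `excitement`, `depression` (five-factor) and `panss_positive`,
#'   `panss_negative`, `panss_general`, `panss_total` (subscales).
#' @export
score_factors <- function(items) {
  if (is.data.frame(items)) items <- unlist(items[1L, , drop = TRUE])
  v <- validate_panss(items)
  f <- lapply(panss_factor_items(), function(ii) as.integer(sum(v[ii])))
  f$panss_positive <- as.integer(sum(v[sprintf("P%d", 1:7)]))
  f$panss_negative <- as.integer(sum(v[sprintf("N%d", 1:7)]))
  f$panss_general  <- as.integer(sum(v[sprintf("G%d", 1:16)]))
  f$panss_total    <- f$panss_positive + f$panss_negative + f$panss_general
  f
}

#' Median-split severity subtyping
#'
#' Dichotomises a cohort at the median of a severity score. With the default
#' rule a subject is labelled `"high"` iff its score strictly exceeds the
#' cohort median, `"low"` otherwise; `rule = "ge"` labels scores at the
#' median as high.
#'
#' @param scores numeric vector of severity scores (>= 2 subjects).
#' @param rule `"gt"` (default, high iff score > median) or `"ge"`.
#' @return list with `labels` (character "high"/"low", same order as
#'   `scores`) and `median`.
#' @export
median_split <- function(scores, rule = c("gt", "ge")) {
  rule <- match.arg(rule)
  if (length(scores) < 2L) stop("median split needs at least 2 subjects")
  med <- stats::median(scores)
  if (all(scores == scores[1L])) {
    warning("all scores identical: every subject labelled low")
    return(list(labels = rep("low", length(scores)), median = med))
  }
  hi <- if (rule == "gt") scores > med else scores >= med
  list(labels = ifelse(hi, "high", "low"), median = med)
}

#' Read a PANSS CSV (one row per subject, 30 item columns)
#'
#' @param path CSV path; must contain the 30 item columns and optionally an
#'   `id` column.
#' @return data.frame of items with rownames from `id` when present.
#' @export
read_panss_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("id" %in% names(df)) {
    rownames(df) <- df$id
    df$id <- NULL
  }
  miss <- setdiff(panss_item_names(), names(df))
  if (length(miss)) stop("PANSS CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df[, panss_item_names(), drop = FALSE]
}
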