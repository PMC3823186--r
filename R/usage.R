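#' Item inventory of the modified Motor Activity Log
#'
#' The 27 daily activities on which respondents rate how frequently they
#' incorporate their residual arm (directly or through a prosthesis), on a
#' three-point frequency scale: never (0), sometimes (1), very often (2).
#' Frequency, not movement quality, is rated.  Item order is fixed; the short
#' codes are the questionnaire's column names in delimited input.
#'
#' @return A data frame with columns `code` (short column name) and `label`
#'   (the activity), 27 rows.
#' @export
mal_items <- function() {
  labels <- c(
    "taking money out of wallet",
    "opening envelope",
    "picking up/lifting glasses",
    "picking up/holding up a phone",
    "wiping off a kitchen counter or other surface",
    "getting out of a car",
    "stabilizing paper while writing",
    "stabilizing dishes while carrying",
    "carrying a cup or a can",
    "carrying bags",
    "getting up from a chair with arm rests",
    "pulling chair away from table before sitting down",
    "holding a book or a magazine/turning pages",
    "typing on a keyboard/pressing mouse buttons",
    "controlling a computer mouse",
    "putting on your socks",
    "putting on your shoes",
    "tying shoe laces",
    "inserting your (intact) arm through a sleeve",
    "putting on makeup base, lotion, or shaving cream on face",
    "washing hand or face",
    "drying your hand or face",
    "combing your hair",
    "buttoning a shirt",
    "zipping up a coat",
    "peeling fruit skin",
    "using a fork or spoon for eating"
  )
  data.frame(code = sprintf("mal%02d", seq_along(labels)), label = labels,
             stringsAsFactors = FALSE)
}

#' Movement laterality index
#'
#' The ratio `(n_intact - n_residual) / (n_intact + n_residual)` over detected
#' movement counts.  A ratio, rather than an absolute number of movements, is
#' used so that whole-body co-movements and differences in hours of recording
#' cancel between the two limbs.  Positive values represent a tendency to use
#' the intact hand more; +1 is exclusive intact-hand use, -1 exclusive
#' residual-arm use, 0 balanced use.
#'
#' Vectorised over both arguments.
#'
#' @param n_intact,n_residual Non-negative movement counts for the intact
#'   wrist and the residual upper arm.
#' @return The laterality index in \[-1, 1\].  Both counts zero is an error
#'   (0 would falsely encode balanced use), not a silent 0.
#' @examples
#' laterality_index(30, 10)  # 0.5
#' @export
laterality_index <- function(n_intact, n_residual) {
  if (length(n_intact) != length(n_residual)) {
    stop("n_intact and n_residual must have the same length", call. = FALSE)
  }
  if (any(!is.finite(n_intact)) || any(!is.finite(n_residual)) ||
      any(n_intact < 0) || any(n_residual < 0)) {
    stop("movement counts must be finite and >= 0", call. = FALSE)
  }
  tot <- n_intact + n_residual
  if (any(tot == 0)) {
    stop("laterality index undefined: both movement counts are zero",
         call. = FALSE)
  }
  (n_intact - n_residual) / tot
}

#' Score a modified Motor Activity Log response
#'
#' Each of the 27 items is scored 0 (never), 1 (sometimes) or 2 (very often);
#' the item sum is divided by 54, placing respondents on a 0--1 scale where
#' higher means more frequent residual-arm incorporation.  Incomplete
#' questionnaires are rejected rather than prorated: the /54 normalisation
#' presumes 27 answered items.
#'
#' @param ratings Numeric vector of exactly 27 item ratings, each in
#'   \{0, 1, 2\}, in the [mal_items()] order.
#' @return The score `sum(ratings) / 54`, in \[0, 1\].
#' @examples
#' score_mal(rep(2, 27))  # scale ceiling: 1
#' @export
score_mal <- function(ratings) {
  if (length(ratings) != 27L) {
    stop("expected 27 item ratings, got ", length(ratings), call. = FALSE)
  }
  bad <- which(!ratings %in% c(0, 1, 2))
  if (length(bad)) {
    stop("item ", bad[1L], " ('", mal_items()$label[bad[1L]],
         "'): rating must be 0, 1 or 2 (got ", ratings[bad[1L]], ")",
         call. = FALSE)
  }
  sum(ratings) / 54
}

#' Chronic pain magnitude
#'
#' Pain intensity (0 'no pain' -- 10 'worst pain imaginable') divided by the
#' frequency code (1 'all the time', 2 'daily', 3 'weekly', 4 'several times
#' per month', 5 'once or less per month').  Because lower frequency codes
#' mean more frequent pain, the quotient grows with both intensity and
#' frequency of pain, reflecting the chronic aspect of the pain.
#'
#' Vectorised over both arguments.
#'
#' @param intensity Pain intensity rating(s) in \[0, 10\].
#' @param frequency Frequency code(s) in \{1, ..., 5\}.
#' @return `intensity / frequency`; higher = worse chronic pain.
#' @export
chronic_pain_score <- function(intensity, frequency) {
  if (length(intensity) != length(frequency)) {
    stop("intensity and frequency must have the same length", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0) || any(intensity > 10)) {
    stop("pain intensity must lie in [0, 10]", call. = FALSE)
  }
  if (any(!frequency %in% 1:5)) {
    stop("pain frequency must be an integer code in 1..5", call. = FALSE)
  }
  intensity / frequency
}

#' Read and score Motor Activity Log questionnaire responses
#'
#' Reads a comma-delimited file with one row per participant and 27 rating
#' columns named by the [mal_items()] short codes (`mal01` ... `mal27`; a
#' template ships in `inst/extdata/mal_questionnaire_template.csv`), and
#' scores each respondent with [score_mal()].  Incomplete rows are rejected.
#'
#' @param path Path to the delimited file.
#' @return A [tibble::tibble()] with `participant_id`, the 27 rating columns
#'   and `mal_score`.
#' @export
read_mal_responses <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  codes <- mal_items()$code
  missing_cols <- setdiff(c("participant_id", codes), names(raw))
  if (length(missing_cols)) {
    stop("'", path, "': missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  scores <- vapply(seq_len(nrow(raw)), function(i) {
    tryCatch(score_mal(as.numeric(raw[i, codes])), error = function(e) {
      stop("participant '", raw$participant_id[i], "': ", conditionMessage(e),
           call. = FALSE)
    })
  }, numeric(1))
  out <- tibble::as_tibble(raw[c("participant_id", codes)])
  out$mal_score <- scores
  out
}

#' Build a per-participant usage record
#'
#' Bundles pooled per-limb movement counts with the derived laterality index.
#'
#' @param participant_id Participant label.
#' @param n_intact,n_residual Pooled movement counts per limb.
#' @return A one-row [tibble::tibble()] with the counts and
#'   `laterality_index`.
#' @export
usage_record <- function(participant_id, n_intact, n_residual) {
  tibble::tibble(
    participant_id = as.character(participant_id),
    n_intact = as.integer(n_intact),
    n_residual = as.integer(n_residual),
    laterality_index = laterality_index(n_intact, n_residual)
  )
}
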