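# Shared alphabet constants and error helpers.

AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Accepted at parse time but flagged: they abstain from consensus votes,
# never match a sharedness window, and poison GRAVY under the default policy.
AA_AMBIGUITY <- c("X", "B", "Z", "U", "O")

GAP_CHAR <- "-"

abort_peptiter <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "peptiter_error"), ...)
}

#' Split residue strings into character matrices/vectors
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort_peptiter(sprintf("`%s` must not be NULL.", name),
                   "peptiter_validation_error")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_peptiter(sprintf("`%s` must be a single finite number.", name),
                   "peptiter_validation_error")
  }
  if (x < lower || x > upper) {
    abort_peptiter(
      sprintf("`%s` = %s violates the bound [%s, %s].", name,
              format(x), format(lower), format(upper)),
      "peptiter_config_error"
    )
  }
  invisible(x)
}
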