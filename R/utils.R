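# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_thr <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_thr(...)
  invisible(TRUE)
}

# Parse free-form booleans from {0,1,yes,no,true,false} (case-insensitive).
parse_flag <- function(x, field = "flag") {
  if (is.logical(x)) return(x)
  key <- tolower(trimws(as.character(x)))
  map <- c("0" = FALSE, "1" = TRUE, "no" = FALSE, "yes" = TRUE,
           "false" = FALSE, "true" = TRUE, "f" = FALSE, "t" = TRUE)
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop_thr("cannot parse %s value(s): %s (allowed: 0/1/yes/no/true/false)",
             field, paste(bad, collapse = ", "))
  }
  out
}

# Modal value after rounding; ties broken toward the smaller value.
modal_value <- function(x, digits = 2) {
  r <- round(x, digits)
  tab <- table(r)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  min(winners)
}

# Population (denominator n) standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
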