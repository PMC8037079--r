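# Internal parsing and validation helpers shared across modules.

#' @noRd
parse_boolean <- function(x) {
  # Accepts 1/0, true/false, yes/no (any case), TRUE/FALSE; "" and NA -> NA.
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  lx <- tolower(x)
  out[lx %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[lx %in% c("0", "false", "f", "no", "n")] <- FALSE
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop(sprintf("unparseable boolean value(s): %s",
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  as.logical(out)
}

#' @noRd
parse_integer <- function(x, field, required = FALSE) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  nonint <- !is.na(out) & out != round(out)
  if (required && any(is.na(x))) {
    stop(sprintf("required field '%s' has missing values", field), call. = FALSE)
  }
  if (any(bad) || any(nonint)) {
    if (required) {
      stop(sprintf("unparseable value(s) in required field '%s': %s", field,
                   paste(unique(x[bad | nonint]), collapse = ", ")),
           call. = FALSE)
    }
    out[bad | nonint] <- NA_real_  # unparseable optional values become missing
  }
  as.integer(round(out))
}

#' @noRd
parse_enum <- function(x, levels, field, default = NA_character_) {
  x <- tolower(trimws(as.character(x)))
  x[x == "" | is.na(x)] <- default
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) x[bad] <- default  # unparseable optional -> default
  x
}

#' @noRd
check_prob <- function(p, name) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
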