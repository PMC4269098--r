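# Exact arbitrary-precision arithmetic for balanced-ternary Codes.
#
# A Code on an n x m incidence matrix has n*m balanced-ternary digits
# (up to 448 at the k = 8 size cap), far beyond 64-bit integer range, so
# values are carried as sign-magnitude decimal bignums. Magnitudes are
# little-endian numeric vectors of base-1e15 limbs: 3 * limb + carry stays
# below 2^53, so double arithmetic is exact throughout.

.BT_BASE <- 1e15
.BT_BASE_DIGITS <- 15L

.bt_limbs_zero <- function() 0

.bt_is_zero <- function(limbs) length(limbs) == 1L && limbs[1L] == 0

# magnitude <- 3 * magnitude + inc, inc in {-1, 0, 1}; magnitude stays >= 0
# for the call patterns used here (inc = -1 only when magnitude >= 1).
.bt_mul3_add <- function(limbs, inc) {
  carry <- inc
  for (i in seq_along(limbs)) {
    x <- 3 * limbs[i] + carry
    if (x < 0) {            # borrow (inc = -1 propagating through zero limbs)
      limbs[i] <- x + .BT_BASE
      carry <- -1
    } else {
      carry <- x %/% .BT_BASE
      limbs[i] <- x - carry * .BT_BASE
    }
  }
  while (carry > 0) {
    limbs <- c(limbs, carry %% .BT_BASE)
    carry <- carry %/% .BT_BASE
  }
  # drop leading zero limbs
  n <- length(limbs)
  while (n > 1L && limbs[n] == 0) n <- n - 1L
  limbs[seq_len(n)]
}

# quotient and remainder of magnitude / 3
.bt_div3 <- function(limbs) {
  r <- 0
  for (i in rev(seq_along(limbs))) {
    x <- r * .BT_BASE + limbs[i]
    q <- x %/% 3
    r <- x - 3 * q
    limbs[i] <- q
  }
  n <- length(limbs)
  while (n > 1L && limbs[n] == 0) n <- n - 1L
  list(q = limbs[seq_len(n)], r = r)
}

.bt_add1 <- function(limbs) {
  carry <- 1
  i <- 1L
  while (carry > 0 && i <= length(limbs)) {
    x <- limbs[i] + carry
    limbs[i] <- x %% .BT_BASE
    carry <- x %/% .BT_BASE
    i <- i + 1L
  }
  if (carry > 0) limbs <- c(limbs, carry)
  limbs
}

.bt_limbs_to_string <- function(limbs, negative = FALSE) {
  if (.bt_is_zero(limbs)) return("0")
  top <- sprintf("%.0f", limbs[length(limbs)])
  rest <- vapply(rev(limbs[-length(limbs)]),
                 function(x) sprintf("%015.0f", x), character(1))
  paste0(if (negative) "-" else "", paste0(top, paste(rest, collapse = "")))
}

.bt_string_to_limbs <- function(s) {
  s <- trimws(s)
  negative <- startsWith(s, "-")
  if (negative || startsWith(s, "+")) s <- substring(s, 2L)
  if (!nzchar(s) || grepl("[^0-9]", s)) {
    stop("not a decimal integer string: ", sQuote(s), call. = FALSE)
  }
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  n <- nchar(s)
  starts <- rev(seq(n, 1L, by = -.BT_BASE_DIGITS))
  limbs <- vapply(starts, function(e) {
    b <- max(1L, e - .BT_BASE_DIGITS + 1L)
    as.numeric(substr(s, b, e))
  }, numeric(1))
  list(limbs = limbs, negative = negative && !.bt_is_zero(limbs))
}

# Balanced-ternary digit vector (most significant first) -> decimal string.
.bt_digits_to_string <- function(digits) {
  first <- which(digits != 0L)[1L]
  if (is.na(first)) return("0")
  negative <- digits[first] < 0L
  sgn <- if (negative) -1L else 1L
  limbs <- .bt_limbs_zero()
  for (d in digits) limbs <- .bt_mul3_add(limbs, sgn * d)
  .bt_limbs_to_string(limbs, negative)
}

# Decimal string -> balanced-ternary digits, left-padded to n_digits.
# Errors when the value does not fit in n_digits.
.bt_string_to_digits <- function(s, n_digits) {
  parsed <- .bt_string_to_limbs(s)
  limbs <- parsed$limbs
  digits <- integer(n_digits)
  for (i in seq_len(n_digits)) {
    if (.bt_is_zero(limbs)) break
    d3 <- .bt_div3(limbs)
    if (d3$r == 2) {        # balanced digit -1, carry one up
      digits[i] <- -1L
      limbs <- .bt_add1(d3$q)
    } else {
      digits[i] <- as.integer(d3$r)
      limbs <- d3$q
    }
  }
  if (!.bt_is_zero(limbs)) {
    stop("value ", s, " out of range for ", n_digits,
         " balanced-ternary digits", call. = FALSE)
  }
  digits <- rev(digits)
  if (parsed$negative) digits <- -digits
  digits
}

# Accepts numeric (exact up to 2^53) or decimal string.
.bt_as_value_string <- function(value) {
  if (is.character(value)) {
    parsed <- .bt_string_to_limbs(value)  # validates
    .bt_limbs_to_string(parsed$limbs, parsed$negative)
  } else if (is.numeric(value)) {
    if (abs(value) >= 2^53 || value != trunc(value)) {
      stop("numeric Code values must be exact integers below 2^53; ",
           "pass a decimal string instead", call. = FALSE)
    }
    sprintf("%.0f", value)
  } else {
    stop("Code value must be numeric or a decimal string", call. = FALSE)
  }
}
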