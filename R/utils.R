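#' @keywords internal
"_PACKAGE"

# Canonical factor levels used throughout
GENDERS <- c("female", "male")
AGE_GROUPS <- c("15-19", "20-24", "25-49")

#' Gender-age strata grid
#'
#' The six gender-by-age-group cells used for distribution matching, in
#' canonical order (female 15-19, female 20-24, female 25-49, then male).
#'
#' @return A data.frame with columns `stratum` (label), `gender`, `age_group`.
#' @export
ga_strata <- function() {
  g <- rep(GENDERS, each = 3L)
  a <- rep(AGE_GROUPS, times = 2L)
  data.frame(
    stratum = paste0(ifelse(g == "female", "F", "M"), sub("-", "_", a)),
    gender = g,
    age_group = a,
    stringsAsFactors = FALSE
  )
}

ga_labels <- function() ga_strata()$stratum

# Label for one (gender, age_group) pair, vectorised
ga_label <- function(gender, age_group) {
  paste0(ifelse(gender == "female", "F", "M"), sub("-", "_", age_group))
}

age_group_of <- function(age_years) {
  cut(age_years, breaks = c(14, 19, 24, 49), labels = AGE_GROUPS)
}

stop_normgaps <- function(msg, class) {
  stop(structure(
    class = c(class, "normgaps_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error <- function(msg) stop_normgaps(msg, "normgaps_config_error")
param_error <- function(msg) stop_normgaps(msg, "normgaps_param_error")
data_error <- function(msg) stop_normgaps(msg, "normgaps_data_error")

#' Weighted proportion
#'
#' @param x Logical or 0/1 vector.
#' @param w Positive weights, recycled checkwise.
#' @param na.rm Drop records with missing `x`.
#' @return Scalar weighted proportion, or `NA` if no usable records.
#' @keywords internal
weighted_prop <- function(x, w, na.rm = TRUE) {
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]
    w <- w[keep]
  }
  if (!length(x)) return(NA_real_)
  sum(w * as.numeric(x)) / sum(w)
}

# Deterministic sub-stream seed derivation. Streams are named so that the
# generator, each resampling replicate and each permutation draw consume
# independent, reproducible seeds below 2^31.
STREAM_IDS <- c(
  generator = 1L, resample = 2L, permutation = 3L, simulation = 4L,
  scenario = 5L, misc = 6L
)

#' Derive a reproducible sub-stream seed
#'
#' @param base_seed Integer master seed.
#' @param stream One of `names(normgaps:::STREAM_IDS)`.
#' @param index Replicate / draw counter (>= 0).
#' @return Integer seed in \[0, 2^31).
#' @export
derive_seed <- function(base_seed, stream = "misc", index = 0L) {
  sid <- STREAM_IDS[[match.arg(stream, names(STREAM_IDS))]]
  # 64-bit-safe mixing in double precision (exact below 2^53)
  h <- (abs(as.numeric(base_seed)) * 69069 + sid * 1299709 + as.numeric(index) * 7559) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# Diff-stable numeric formatting for CSV outputs (6 significant digits)
fmt_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 6L, format = "g"))
}

write_tidy_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
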