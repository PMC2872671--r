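#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   bind_rows left_join n distinct across all_of desc row_number
#' @importFrom purrr map map_chr map_int map_dbl map2 imap pmap keep
#' @importFrom stats var setNames runif
#' @importFrom utils combn head
NULL

# derive a reproducible child seed from a user seed and a stream label.
# The generator itself is used as the mixing function (seed the RNG, burn
# a stream-dependent number of draws, emit one integer): an affine map of
# sequential user seeds fed straight to set.seed() produces noticeably
# correlated simulated datasets, which this scrambling removes.  Output
# stays below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  iv <- utf8ToInt(stream)
  h <- sum(iv * seq_along(iv))
  base <- as.integer((as.numeric(seed) + h) %% 2147483629)
  burn <- 17L + (h %% 13L)
  withr::with_seed(base, sample.int(2147483646L, burn)[burn])
}

assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  invisible(as.integer(x))
}
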