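# internal helpers shared across modules

# population variance / sd (divide by n): aggregates are descriptors of the
# response, not estimators of a super-population moment
pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

pop_sd <- function(x) sqrt(pop_var(x))

# mean/median/min/max that return NA (not Inf/NaN) on empty input
agg_or_na <- function(x, fun) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  fun(x)
}

stop_vf <- function(..., class) {
  rlang::abort(paste0(...), class = paste0("vfforage_", class))
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_vf(what, " is missing required column(s): ",
            paste(missing, collapse = ", "), class = "bad_input")
  }
}
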