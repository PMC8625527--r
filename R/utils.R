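# Internal helpers shared across modules.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Coerce a sample -> group mapping into a factor with levels control/treated,
# named by sample id. Accepts a named vector or a data.frame(sample_id, group).
as_group_factor <- function(groups) {
  if (is.data.frame(groups)) {
    need_cols(groups, c("sample_id", "group"), "group table")
    g <- as.character(groups$group)
    names(g) <- as.character(groups$sample_id)
    groups <- g
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named by sample id", call. = FALSE)
  bad <- setdiff(unique(as.character(groups)), c("control", "treated"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out <- factor(as.character(groups), levels = c("control", "treated"))
  names(out) <- names(groups)
  out
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (x < lower || x > upper)
    stop("'", name, "' must be in [", lower, ", ", upper, "]", call. = FALSE)
  if (integerish && x != round(x))
    stop("'", name, "' must be an integer", call. = FALSE)
  invisible(x)
}

# Row means / variances of a matrix restricted to given columns, NA-aware.
row_moments <- function(x) {
  n <- rowSums(!is.na(x))
  s <- rowSums(x, na.rm = TRUE)
  m <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums(x * x, na.rm = TRUE)
  v <- ifelse(n > 1, (ss - n * m^2) / (n - 1), NA_real_)
  v[v < 0] <- 0  # guard tiny negative round-off
  list(n = n, mean = m, var = v)
}
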