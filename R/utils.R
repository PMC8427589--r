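# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' @noRd
is_count_col <- function(nm) startsWith(nm, "count_")

#' Species names encoded in a visits table's count columns
#' @noRd
visit_species <- function(visits) {
  sub("^count_", "", grep("^count_", names(visits), value = TRUE))
}

# Polynomial rolling hash over the deparsed object; stable fingerprint
# for run metadata without a digest dependency. Mod 2^31-1 keeps all
# intermediates exactly representable as doubles.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# All permutations of 1..n as an n!-row matrix; only used for exact
# small-sample rank-correlation p-values (n <= 9).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# Seed scoping: every stochastic operation draws from its own stream so
# regeneration with the same (operation, seed) pair is bit-identical.
with_seed <- function(seed, expr) {
  stop_if_not(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
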