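# Internal helpers shared across the package.

#' @importFrom rlang %||% abort
NULL

# Classed errors so callers/tests can distinguish failure modes.
dvm_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "dvmetric_error"))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# `seed = NULL` means "use the session RNG as-is".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic derived seeds, kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 1013904223) %% 2147483647)
}

# Student-t 95% confidence interval for a vector of replicate values.
t_ci95 <- function(values) {
  m <- length(values)
  mu <- mean(values)
  if (m < 2 || stats::sd(values) == 0) {
    return(c(low = mu, high = mu))
  }
  half <- stats::qt(0.975, df = m - 1) * stats::sd(values) / sqrt(m)
  c(low = mu - half, high = mu + half)
}

is_discrete_vector <- function(v) {
  is.factor(v) || is.character(v) || is.logical(v)
}

# Coerce a sample collection (vector, factor, matrix, data frame) into
# continuous (numeric matrix) and discrete (character matrix) blocks.
as_sample_blocks <- function(x, arg = "x") {
  if (is.null(dim(x))) {
    x <- if (is_discrete_vector(x)) {
      data.frame(v1 = as.character(x), stringsAsFactors = FALSE)
    } else {
      data.frame(v1 = as.numeric(x))
    }
  }
  if (is.matrix(x)) {
    x <- as.data.frame(x, stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (ncol(x) == 0 || nrow(x) == 0) {
    dvm_abort(sprintf("`%s` has no observations", arg), "dvmetric_error_empty_input")
  }
  disc <- vapply(x, is_discrete_vector, logical(1))
  cont <- NULL
  if (any(!disc)) {
    cont <- as.matrix(as.data.frame(lapply(x[!disc], as.numeric)))
    storage.mode(cont) <- "double"
  }
  dmat <- NULL
  if (any(disc)) {
    dmat <- as.matrix(as.data.frame(lapply(x[disc], as.character),
                                    stringsAsFactors = FALSE))
  }
  list(cont = cont, disc = dmat, n = nrow(x))
}

# Collapse the rows of sample blocks into one categorical key per sample.
# `digest` optionally maps continuous coordinates through a quantizer first.
blocks_key <- function(blocks) {
  parts <- list()
  if (!is.null(blocks$cont)) {
    parts <- c(parts, lapply(seq_len(ncol(blocks$cont)),
                             function(j) format(blocks$cont[, j], digits = 15)))
  }
  if (!is.null(blocks$disc)) {
    parts <- c(parts, lapply(seq_len(ncol(blocks$disc)),
                             function(j) blocks$disc[, j]))
  }
  do.call(paste, c(parts, sep = "\r"))
}

check_paired <- function(nx, ny, what = c("x", "y")) {
  if (nx != ny) {
    dvm_abort(
      sprintf("`%s` and `%s` must be paired samples of equal length (%d vs %d)",
              what[1], what[2], nx, ny),
      "dvmetric_error_paired"
    )
  }
}
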