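#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' restoring the previous RNG state afterwards so that library calls do not
#' perturb a caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# flatten a nested list of numeric arrays into one vector
flatten_params <- function(par) unlist(par, use.names = FALSE)

# rebuild a nested parameter list from a flat vector using `template`'s shape
unflatten_params <- function(vec, template) {
  i <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    len <- length(x)
    out <- vec[(i + 1L):(i + len)]
    i <<- i + len
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  out <- fill(template)
  stopifnot(i == length(vec))
  out
}

# indices (in flattened order) of a named top-level component of a param list
flat_index_of <- function(par, component) {
  lens <- vapply(par, function(x) length(unlist(x, use.names = FALSE)), 0L)
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  k <- match(component, names(par))
  seq.int(starts[k], ends[k])
}

# row-wise addition of a bias vector
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# small non-cryptographic content hash (FNV-1a, 32 bit) used to tag
# serialized model archives with their configuration
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

largest_remainder_round <- function(x, total) {
  # round nonnegative reals to integers summing exactly to `total`
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}
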