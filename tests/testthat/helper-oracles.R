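# Independent oracles used to validate the package implementations.
# These deliberately share no code with the package: the scanner oracle is
# a lookahead-regex sweep, the alignment oracle a cubic general-gap-cost
# dynamic program, and tree truths come from hand-built additive matrices.

# --- motif scanner oracle: overlapping regex windows -------------------
oracle_scan <- function(seqstr) {
  find <- function(re) {
    m <- gregexpr(re, seqstr, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  can <- find("(?=R..[ACGP].G..)")
  rx4 <- setdiff(find("(?=R....G..)"), can)
  rx5 <- find("(?=R.....G..)")
  out <- rbind(
    if (length(can)) data.frame(start = can, length = 8L,
                                configuration = "canonical"),
    if (length(rx4)) data.frame(start = rx4, length = 8L,
                                configuration = "rx4"),
    if (length(rx5)) data.frame(start = rx5, length = 9L,
                                configuration = "rx5"))
  if (is.null(out))
    return(data.frame(start = integer(0), length = integer(0),
                      configuration = character(0)))
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- alignment oracle: cubic DP with general gap cost g(k) = open + k*ext
oracle_global_score <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  sub <- scheme$matrix; go <- scheme$gap_open; ge <- scheme$gap_extend
  n <- length(A); m <- length(B)
  S <- matrix(-Inf, n + 1L, m + 1L)
  S[1L, 1L] <- 0
  for (i in 0:n) for (j in 0:m) {
    if (i == 0L && j == 0L) next
    best <- -Inf
    if (i > 0L && j > 0L) best <- S[i, j] + sub[A[i], B[j]]
    if (i > 0L) for (k in 1:i)
      best <- max(best, S[i - k + 1L, j + 1L] - (go + k * ge))
    if (j > 0L) for (k in 1:j)
      best <- max(best, S[i + 1L, j - k + 1L] - (go + k * ge))
    S[i + 1L, j + 1L] <- best
  }
  S[n + 1L, m + 1L]
}

oracle_local_score <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  sub <- scheme$matrix; go <- scheme$gap_open; ge <- scheme$gap_extend
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in 1:max(n, 1L)) for (j in 1:max(m, 1L)) {
    if (i > n || j > m) next
    v <- S[i, j] + sub[A[i], B[j]]
    for (k in 1:i) v <- max(v, S[i - k + 1L, j + 1L] - (go + k * ge))
    for (k in 1:j) v <- max(v, S[i + 1L, j - k + 1L] - (go + k * ge))
    S[i + 1L, j + 1L] <- max(0, v)
    best <- max(best, S[i + 1L, j + 1L])
  }
  best
}

# --- random sequences / alignments -------------------------------------
random_protein <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                             "H", "I", "K", "L", "M", "N",
                                             "P", "Q", "R", "S", "T", "V",
                                             "W", "Y"),
                           x_rate = 0) {
  ch <- sample(alphabet, len, replace = TRUE)
  if (x_rate > 0) {
    mask <- runif(len) < x_rate
    ch[mask] <- "X"
  }
  paste(ch, collapse = "")
}

random_alignment <- function(nrow = 5L, ncol = 40L, gap_rate = 0.1) {
  repeat {
    m <- matrix(sample(c("A", "C", "D", "E", "G", "R"), nrow * ncol,
                       replace = TRUE), nrow, ncol)
    gaps <- matrix(runif(nrow * ncol) < gap_rate, nrow, ncol)
    m[gaps] <- "-"
    if (all(colSums(m != "-") > 0L)) break
  }
  new_alignment(paste0("r", seq_len(nrow)),
                apply(m, 1L, paste, collapse = ""))
}

# --- random additive distance matrix from a random tree ----------------
random_additive <- function(n = 6L) {
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  list(tree = tr, dm = stats::cophenetic(tr)[tr$tip.label, tr$tip.label])
}
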