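# Shared helpers for the test suite: all fixtures are generated in code.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random scoring scheme with thresholds disabled, for oracle-equivalence
# batteries (gap_extend >= 1 is a scoring_scheme() requirement).
rand_scoring <- function() {
  scoring_scheme(match = sample(1:6, 1), mismatch = sample(0:7, 1),
                 gap_open = sample(0:7, 1), gap_extend = sample(1:5, 1),
                 min_score = 1L, min_span_bp = 1L)
}

# A random read, biased towards repeat-containing sequence.
rand_read <- function(motif, max_len = 200L) {
  if (runif(1) < 0.4) {
    r <- rand_dna(sample(5:max_len, 1))
  } else {
    k <- sample(1:15, 1)
    r <- paste0(rand_dna(sample(0:20, 1)), strrep(motif, k),
                rand_dna(sample(0:20, 1)))
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    for (e in seq_len(sample(0:4, 1))) {
      p <- sample(length(ch), 1)
      ch[p] <- sample(c("", "A", "C", "G", "T", "AA", "CT"), 1)
    }
    r <- paste(ch, collapse = "")
  }
  if (nchar(r) == 0L) "A" else substr(r, 1, max_len)
}

expect_same_alignment <- function(a, b) {
  expect_identical(is.null(a), is.null(b))
  if (is.null(a)) return(invisible())
  f <- c("score", "repeat_count", "matches", "substitutions", "insertions",
         "deletions", "start", "end", "strand")
  expect_identical(unlist(a[f]), unlist(b[f]))
}

# Independent exact Mann-Whitney oracle: U from its set definition
# (pair counts, ties worth 1/2), null distribution by enumerating every
# assignment of the pooled values to the first group.
mw_exact_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u <- u_of(x, y)
  pool <- c(x, y)
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, function(idx) u_of(pool[idx], pool[-idx]))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(us <= u + eps), mean(us >= u - eps)))
  list(U = u, p_value = p)
}
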