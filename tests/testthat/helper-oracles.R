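## Independent brute-force oracles used to verify the package's operations.
## These deliberately share no code with the implementation paths they check.

## top-n quantification: the best sum over all subsets of size <= n_top.
oracle_topn <- function(areas, n_top = 3) {
  if (!length(areas)) return(NA_real_)
  k <- min(n_top, length(areas))
  max(utils::combn(areas, k, sum))
}

## Tryptic digestion: enumerate every substring and keep those whose ends lie
## on cleavage boundaries with at most max_missed internal sites.
oracle_digest <- function(sequence, max_missed, cleave_before_proline) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  is_site <- if (n > 1) {
    vapply(seq_len(n - 1), function(p) {
      ch[p] %in% c("K", "R") && (cleave_before_proline || ch[p + 1] != "P")
    }, logical(1))
  } else {
    logical(0)
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      left_ok <- i == 1 || is_site[i - 1]
      right_ok <- j == n || is_site[j]
      if (left_ok && right_ok) {
        internal <- if (j > i) sum(is_site[i:(j - 1)]) else 0L
        if (internal <= max_missed) {
          out[[length(out) + 1L]] <- data.frame(
            peptide = substr(sequence, i, j), start = i, end = j,
            missed = internal, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

digest_key <- function(d) sort(paste(d$peptide, d$start, d$end, d$missed))

## Benjamini-Hochberg by its step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) min(ps[i:m] * m / (i:m)), numeric(1))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## Upper hypergeometric tail by direct summation of binomial-coefficient
## ratios.
oracle_hyper_tail <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

## One-way F via R's linear-model machinery (independent of the package's
## sum-of-squares path).
f_oracle <- function(v, g) {
  stats::anova(stats::lm(v ~ factor(g)))[1, "F value"]
}

## Exact permutation p by enumerating all n! value permutations (equal
## weights; multiset duplicates cancel).
all_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]))
  }))
}

oracle_perm_p <- function(v, g) {
  f0 <- f_oracle(v, g)
  fs <- apply(all_perms(v), 1L, f_oracle, g = g)
  mean(fs >= f0 - 1e-10 * (1 + abs(f0)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## Minimal hand-built peptide record table.
make_records <- function(sequence, location_id, peak_area,
                         protein_accession = "P1", modifications = "",
                         significance = 60, is_unique = TRUE) {
  if (length(sequence) == 0L) {
    return(data.frame(sequence = character(0), modifications = character(0),
                      protein_accession = character(0),
                      location_id = character(0), peak_area = numeric(0),
                      significance = numeric(0), is_unique = logical(0)))
  }
  data.frame(sequence = sequence, modifications = modifications,
             protein_accession = protein_accession,
             location_id = location_id, peak_area = peak_area,
             significance = significance, is_unique = is_unique,
             stringsAsFactors = FALSE)
}

random_aa_string <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}
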