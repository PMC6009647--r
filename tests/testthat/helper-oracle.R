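## Independent oracles used by the tests.

## exhaustive window-scan motif finder (both strands), independent of the
## Biostrings-based implementation
brute_find_sites <- function(sequence, motif) {
  n <- nchar(sequence); w <- nchar(motif)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(motif, "")[[1]]]), collapse = "")
  pos <- integer(); strand <- character()
  for (i in seq_len(n - w + 1)) {
    win <- substr(sequence, i, i + w - 1)
    if (win == motif) { pos <- c(pos, i - 1L); strand <- c(strand, "+") }
    else if (win == rc && rc != motif) {
      pos <- c(pos, i - 1L); strand <- c(strand, "-")
    }
  }
  ord <- order(pos, strand)
  data.frame(position = pos[ord], strand = strand[ord],
             stringsAsFactors = FALSE)
}

## exhaustive enumeration of all monotone label<->site matchings under the
## alignment objective; independent of the dynamic program
oracle_align <- function(labels, sites, params) {
  L <- length(labels); S <- length(sites)
  score_of <- function(pairs) {
    sc <- 0
    if (nrow(pairs)) {
      d <- abs(labels[pairs[, 1]] - sites[pairs[, 2]])
      if (any(d > params$match_width + 1e-9)) return(-Inf)
      sc <- sum(if (params$flat_score) rep(params$match_score, length(d))
                else params$match_score * pmax(0, 1 - d / params$match_width))
    }
    sc <- sc - (L - nrow(pairs)) * params$extra_label_penalty
    if (nrow(pairs)) {
      skipped <- setdiff(seq_len(S), pairs[, 2])
      interior <- if (params$free_ends)
        skipped[skipped > min(pairs[, 2]) & skipped < max(pairs[, 2])]
      else skipped
      sc <- sc - length(interior) * params$miss_site_penalty
    } else if (!params$free_ends) {
      sc <- sc - S * params$miss_site_penalty
    }
    sc
  }
  best <- list(score = -Inf, matches = -1L,
               pairs = matrix(integer(), ncol = 2))
  rec <- function(i, j, pairs) {
    if (i > L) {
      sc <- score_of(pairs)
      if (sc > best$score + 1e-9 ||
          (sc > best$score - 1e-9 && nrow(pairs) > best$matches)) {
        best <<- list(score = sc, matches = nrow(pairs), pairs = pairs)
      }
      return(invisible())
    }
    rec(i + 1, j, pairs)                       # label i unmatched
    if (j <= S) {
      for (jj in j:S)                          # label i matched to site jj
        if (abs(labels[i] - sites[jj]) <= params$match_width + 1e-9)
          rec(i + 1, jj + 1, rbind(pairs, c(i, jj)))
    }
  }
  rec(1, 1, matrix(integer(), ncol = 2))
  best
}

random_align_instance <- function(max_labels = 6, max_sites = 5,
                                  span = 1500) {
  L <- sample(0:max_labels, 1)
  S <- sample(1:max_sites, 1)
  list(labels = sort(runif(L, 0, span)), sites = sort(runif(S, 0, span)))
}
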