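# Independent brute-force oracles used by the property tests. These are
# deliberately naive re-derivations that share no code with the package
# implementations they check.

# Standard genetic code, written out by hand.
ORACLE_CODON <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_revcomp <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(dna, "")[[1]]]), collapse = "")
}

oracle_translate <- function(dna, offset) {
  chars <- strsplit(dna, "")[[1]]
  n <- length(chars) - offset
  out <- character(0)
  for (i in seq_len(n %/% 3)) {
    codon <- paste(chars[offset + (3 * i - 2):(3 * i)], collapse = "")
    out[i] <- if (grepl("N", codon)) "X" else ORACLE_CODON[[codon]]
  }
  paste(out, collapse = "")
}

# Enumerate every (ATG, first in-frame stop) ORF in all six frames; apply the
# longest-per-stop rule; coordinates 0-based half-open on the forward strand.
oracle_orfs <- function(seq, min_aa, longest_per_stop = TRUE) {
  len <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (frame in 0:2) {
      aa <- strsplit(oracle_translate(s, frame), "")[[1]]
      prev_stop <- 0L
      for (st in which(aa == "*")) {
        ms <- which(aa == "M")
        ms <- ms[ms > prev_stop & ms < st]
        if (longest_per_stop && length(ms)) ms <- min(ms)
        for (m in ms) {
          if (st - m < min_aa) next
          a <- frame + 3 * (m - 1)
          b <- frame + 3 * st
          if (strand == "-") { tmp <- a; a <- len - b; b <- len - tmp }
          res[[length(res) + 1]] <- list(
            strand = strand, frame = frame, start = a, end = b,
            aa_seq = paste(aa[m:(st - 1)], collapse = ""))
        }
        prev_stop <- st
      }
    }
  }
  res
}

orf_key <- function(o) sprintf("%s/%d/%d/%d/%s", o$strand, o$frame, o$start,
                               o$end, o$aa_seq)

# Position-by-position degenerate-pattern scan. `positions` is a list of
# allowed-residue vectors; a full 20-residue set is the wildcard and the only
# kind of position an X residue can match.
oracle_scan <- function(aa, positions) {
  chars <- strsplit(aa, "")[[1]]
  k <- length(positions)
  hits <- integer(0)
  full <- 20L
  for (s in seq_len(max(0, length(chars) - k + 1))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      r <- chars[s + j - 1]
      wild <- length(positions[[j]]) == full
      if (!wild && !(r %in% positions[[j]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s - 1L)
  }
  hits
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_pattern_text <- function() {
  k <- sample(2:6, 1)
  toks <- vapply(seq_len(k), function(i) {
    if (runif(1) < 0.2) "x"
    else {
      m <- sample(1:4, 1)
      res <- sample(AA20, m)
      if (m == 1) res else paste0("[", paste(res, collapse = ""), "]")
    }
  }, "")
  paste(toks, collapse = "-")
}

random_protein <- function(n, p_x = 0.02) {
  paste(sample(c(AA20, "X"), n, replace = TRUE,
               prob = c(rep((1 - p_x) / 20, 20), p_x)), collapse = "")
}

# Hand sum-of-squares one-way ANOVA.
oracle_anova_f <- function(values, groups) {
  gs <- split(values, groups)
  grand <- mean(values)
  ssb <- sum(vapply(gs, function(x) length(x) * (mean(x) - grand)^2, 0))
  ssw <- sum(vapply(gs, function(x) sum((x - mean(x))^2), 0))
  dfb <- length(gs) - 1
  dfw <- length(values) - length(gs)
  list(f = (ssb / dfb) / (ssw / dfw), dfb = dfb, dfw = dfw)
}

# Random additive distance matrix from a random binary tree with known
# positive edge lengths; returns the matrix and the generating topology.
random_additive_matrix <- function(n_taxa) {
  tr <- ape::unroot(ape::rtree(n_taxa, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  d <- stats::cophenetic(tr)
  ord <- sort(rownames(d))
  list(d = d[ord, ord], tree = tr)
}

# Exhaustive-search NJ oracle: among all unrooted leaf-labelled topologies,
# pick the one whose least-squares edge fit minimises the additivity error.
oracle_best_topology <- function(d) {
  labs <- rownames(d)
  cands <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  pair_idx <- utils::combn(length(labs), 2)
  y <- d[t(pair_idx)]
  best <- NULL; best_rss <- Inf
  for (ti in seq_along(cands)) {
    tr <- cands[[ti]]   # [[ materialises tip labels from the compressed set
    A <- matrix(0, ncol(pair_idx), nrow(tr$edge))
    for (p in seq_len(ncol(pair_idx))) {
      path_nodes <- ape::nodepath(tr, pair_idx[1, p], pair_idx[2, p])
      for (q in seq_len(length(path_nodes) - 1)) {
        e <- which((tr$edge[, 1] == path_nodes[q] & tr$edge[, 2] == path_nodes[q + 1]) |
                   (tr$edge[, 2] == path_nodes[q] & tr$edge[, 1] == path_nodes[q + 1]))
        A[p, e] <- 1
      }
    }
    fit <- stats::lm.fit(A, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- tr }
  }
  best
}

same_topology <- function(t1, t2) {
  isTRUE(all.equal(as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))), 0))
}

# Convenience: a canonical passing cystatin-like sequence with known spacing.
demo_positive <- function(central = "QVVSG", cw = "PW", tail = "AEFHIKLMRST") {
  paste0("M", "ACDEF", "GG", "HIKLMRSTVACD",  # GG ends at 8
         "LARFAVDEHN",                        # helix
         "EFHIKLMRSTVACDEFHIKL",              # 20 spacer -> central at 50
         central,
         "ACDEFHIKLMRSTVACDEFHIKLMR",         # 25 spacer -> cw at 80
         cw, tail)
}
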