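# Chromatin-state segmentation: Poisson binarization of mark tracks and a
# 6-state multivariate Bernoulli hidden Markov model trained on the
# concatenation of all tissues (one shared model, decoded per tissue),
# following the ChromHMM conventions (200-bp bins, Poisson p < 1e-4
# binarization, posterior decoding).

#' Binarize a signal track against a Poisson background
#'
#' The genome-wide mean bin count defines the background rate lambda; a bin
#' is called "on" iff the Poisson upper-tail probability of its count,
#' `P(X >= count | lambda)`, falls below `p_threshold`.
#'
#' @param track a [signal_track()] of non-negative counts
#' @param p_threshold tail-probability cutoff (ChromHMM default 1e-4)
#' @return list per chromosome of integer 0/1 vectors; the count threshold
#'   actually applied is attached as attribute `threshold_count`
#' @export
binarize_track <- function(track, p_threshold = 1e-4) {
  stopifnot(inherits(track, "signal_track"))
  all_v <- unlist(track$values, use.names = FALSE)
  if (any(all_v < 0)) stopf("binarize_track expects non-negative counts")
  lambda <- mean(all_v)
  if (lambda == 0) {
    warnf("all-zero track: lambda = 0, returning all-zero binarization")
    out <- lapply(track$values, function(v) integer(length(v)))
    attr(out, "threshold_count") <- Inf
    return(out)
  }
  thr <- poisson_threshold_count(lambda, p_threshold)
  out <- lapply(track$values, function(v) as.integer(v >= thr))
  attr(out, "threshold_count") <- thr
  attr(out, "lambda") <- lambda
  out
}

#' Assemble per-tissue binary mark matrices
#'
#' Binarizes one track per mark and binds them into per-chromosome
#' bins x marks 0/1 matrices sharing one bin grid.
#'
#' @param tracks named list of [signal_track()]s, one per mark, e.g.
#'   `list(ATAC = ..., H3K4me3 = ..., H3K27ac = ...)`
#' @param p_threshold Poisson tail cutoff passed to [binarize_track()]
#' @return named list per chromosome of integer matrices with mark columns
#' @export
binarize_marks <- function(tracks, p_threshold = 1e-4) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  bin <- lapply(tracks, binarize_track, p_threshold = p_threshold)
  chroms <- names(bin[[1]])
  out <- lapply(chroms, function(ch) {
    m <- do.call(cbind, lapply(bin, function(b) b[[ch]]))
    colnames(m) <- names(tracks)
    m
  })
  names(out) <- chroms
  out
}

# encode rows of a 0/1 matrix as pattern indices 1 .. 2^M
encode_patterns <- function(x) {
  as.integer(x %*% (2^(seq_len(ncol(x)) - 1))) + 1L
}

# P x K emission likelihood table for all 2^M binary patterns
pattern_likelihoods <- function(emissions) {
  K <- nrow(emissions); M <- ncol(emissions)
  P <- 2^M
  bits <- t(vapply(seq_len(P) - 1L,
                   function(p) as.integer(intToBits(p))[seq_len(M)],
                   integer(M)))
  ep <- matrix(1, P, K)
  for (m in seq_len(M)) {
    ep <- ep * outer(bits[, m], emissions[, m], function(b, e)
      ifelse(b == 1, e, 1 - e))
  }
  ep
}

#' Train a multivariate Bernoulli-emission HMM by Baum-Welch
#'
#' One model is fitted to the concatenation of all supplied binary
#' sequences (typically per tissue x chromosome), with per-mark independent
#' Bernoulli emissions. The best of `n_restarts` EM runs by log-likelihood
#' is returned; within each run the log-likelihood is asserted to be
#' non-decreasing and iteration stops when the increase drops below `tol`.
#'
#' Restarts are initialized from distinct observed mark patterns
#' (frequency-weighted, jittered), which keeps EM away from collapsed
#' solutions when the states are pattern-separated.
#'
#' @param binmats list of integer 0/1 matrices (bins x marks), or a single
#'   matrix; all must share the same mark columns
#' @param K number of hidden states (default 6)
#' @param n_restarts number of EM restarts (default 5)
#' @param seed integer seed controlling all restart initializations
#' @param max_iter,tol EM stopping rule (at most `max_iter` iterations or
#'   log-likelihood increase below `tol`)
#' @return object of class `bernoulli_hmm` with elements `emissions`
#'   (K x marks), `transitions`, `init`, `loglik`, `n_iter`, `converged`
#' @export
train_hmm <- function(binmats, K = 6, n_restarts = 5, seed = 1,
                      max_iter = 500, tol = 1e-4) {
  if (is.matrix(binmats)) binmats <- list(binmats)
  stopifnot(length(binmats) >= 1, K >= 2)
  M <- ncol(binmats[[1]])
  marks <- colnames(binmats[[1]]) %||% paste0("mark", seq_len(M))
  for (x in binmats) {
    if (ncol(x) != M) stopf("all sequences must share the mark columns")
    if (!all(x %in% c(0L, 1L))) stopf("binary matrices must contain only 0/1")
  }
  pats <- lapply(binmats, encode_patterns)
  X <- lapply(binmats, function(x) matrix(as.numeric(x), nrow(x), M))
  obs_pat <- sort(unique(unlist(pats)))
  if (K > length(obs_pat))
    warnf("K = %d exceeds the %d distinct observed emission patterns; states may collapse",
          K, length(obs_pat))
  pat_freq <- table(factor(unlist(pats), levels = seq_len(2^M)))
  bits_all <- t(vapply(seq_len(2^M) - 1L,
                       function(p) as.integer(intToBits(p))[seq_len(M)],
                       integer(M)))

  run_em <- function(em0, tr0, pi0) {
    em <- em0; tr <- tr0; pi0v <- pi0
    prev_ll <- -Inf; ll <- NA_real_; converged <- FALSE; it <- 0L
    for (it in seq_len(max_iter)) {
      ep <- pattern_likelihoods(em)
      ll <- 0
      num_e <- matrix(0, K, M); den_e <- numeric(K)
      tr_num <- matrix(0, K, K); init_num <- numeric(K)
      for (s in seq_along(pats)) {
        B <- ep[pats[[s]], , drop = FALSE]
        fb <- hmm_forward_backward(B, tr, pi0v)
        if (!is.finite(fb$loglik)) return(NULL)
        ll <- ll + fb$loglik
        g <- fb$gamma
        num_e <- num_e + crossprod(g, X[[s]])
        den_e <- den_e + colSums(g)
        tr_num <- tr_num + fb$xisum
        init_num <- init_num + g[1, ]
      }
      if (ll < prev_ll - 1e-8 * max(1, abs(ll)))
        stopf("Baum-Welch log-likelihood decreased (%.6f -> %.6f)", prev_ll, ll)
      if (is.finite(prev_ll) && ll - prev_ll < tol) { converged <- TRUE; break }
      prev_ll <- ll
      em <- num_e / pmax(den_e, .Machine$double.eps)
      em <- pmin(pmax(em, 1e-6), 1 - 1e-6)
      tr <- tr_num / pmax(rowSums(tr_num), .Machine$double.eps)
      tr <- tr / rowSums(tr)
      pi0v <- init_num / sum(init_num)
    }
    list(emissions = em, transitions = tr, init = pi0v, loglik = ll,
         n_iter = it, converged = converged)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + r, {
      avail <- obs_pat
      probs <- as.numeric(pat_freq[avail]) / sum(pat_freq[avail])
      if (length(avail) >= K) {
        proto <- sample(avail, K, prob = probs)
      } else {
        proto <- sample(avail, K, replace = TRUE, prob = probs)
      }
      em0 <- 0.15 + 0.7 * bits_all[proto, , drop = FALSE]
      em0 <- pmin(pmax(em0 + matrix(runif(K * M, -0.08, 0.08), K, M),
                       0.05), 0.95)
      tr0 <- matrix(0.2 / (K - 1), K, K); diag(tr0) <- 0.8
      run_em(em0, tr0, rep(1 / K, K))
    })
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) stopf("all EM restarts failed (zero-likelihood data)")
  dimnames(best$emissions) <- list(paste0("S", seq_len(K)), marks)
  structure(c(best, list(K = K, marks = marks)), class = "bernoulli_hmm")
}

#' @export
print.bernoulli_hmm <- function(x, ...) {
  cat(sprintf("Bernoulli HMM: %d states, marks: %s, loglik %.2f (%s in %d iter)\n",
              x$K, paste(x$marks, collapse = "/"), x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  print(round(x$emissions, 3))
  invisible(x)
}

#' Compute the forward log-likelihood of a binary sequence under a model
#'
#' @param model `bernoulli_hmm`
#' @param binmat bins x marks 0/1 matrix
#' @return log-likelihood (numeric scalar)
#' @export
hmm_loglik <- function(model, binmat) {
  ep <- pattern_likelihoods(model$emissions)
  B <- ep[encode_patterns(binmat), , drop = FALSE]
  hmm_forward_backward(B, model$transitions, model$init)$loglik
}

#' Simulate a binary mark sequence from a Bernoulli HMM
#'
#' @param model `bernoulli_hmm` (or a list with emissions/transitions/init)
#' @param n_bins sequence length
#' @param seed integer seed
#' @return list with `states` (integer path) and `x` (bins x marks matrix)
#' @export
simulate_hmm_sequence <- function(model, n_bins, seed = 1) {
  K <- nrow(model$emissions); M <- ncol(model$emissions)
  with_seed(seed, {
    states <- integer(n_bins)
    states[1] <- sample.int(K, 1, prob = model$init)
    for (t in seq_len(n_bins - 1L))
      states[t + 1L] <- sample.int(K, 1, prob = model$transitions[states[t], ])
    x <- matrix(rbinom(n_bins * M, 1, model$emissions[states, ]), n_bins, M)
    colnames(x) <- colnames(model$emissions)
    list(states = states, x = x)
  })
}

#' Decode a binary mark matrix into a chromatin-state segmentation
#'
#' Per-bin posterior-maximum decoding (the ChromHMM MakeSegmentation
#' convention); Viterbi decoding is available via `method = "viterbi"`.
#' Adjacent same-state bins are merged into intervals.
#'
#' @param model trained `bernoulli_hmm`
#' @param binmats named list per chromosome of bins x marks 0/1 matrices
#'   (one tissue), or a single matrix (treated as chromosome "chr")
#' @param bin_size bin width in bp (default 200)
#' @param method "posterior" (default) or "viterbi"
#' @return object of class `segmentation`: list with `states` (per-chrom
#'   integer vectors), `intervals` (chrom/start/end/state data frame),
#'   `bin_size`, and `labels` (NULL until [label_states()] is applied)
#' @export
decode_states <- function(model, binmats, bin_size = 200,
                          method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  if (is.matrix(binmats)) binmats <- list(chr = binmats)
  if (any(vapply(binmats, ncol, 0L) != ncol(model$emissions)))
    stopf("mark count mismatch between model (%d) and data",
          ncol(model$emissions))
  ep <- pattern_likelihoods(model$emissions)
  states <- lapply(binmats, function(x) {
    B <- ep[encode_patterns(x), , drop = FALSE]
    if (method == "posterior") {
      fb <- hmm_forward_backward(B, model$transitions, model$init)
      max.col(fb$gamma, ties.method = "first")
    } else {
      viterbi_path(B, model$transitions, model$init)
    }
  })
  ivs <- do.call(rbind, lapply(names(states), function(ch) {
    s <- states[[ch]]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(chrom = ch, start = starts * bin_size, end = ends * bin_size,
               state = r$values, stringsAsFactors = FALSE)
  }))
  structure(list(states = states, intervals = ivs,
                 bin_size = as.integer(bin_size), labels = NULL),
            class = "segmentation")
}

viterbi_path <- function(B, trans, init) {
  T_ <- nrow(B); K <- ncol(B)
  lB <- log(B); lT <- log(trans)
  delta <- log(init) + lB[1, ]
  psi <- matrix(0L, T_, K)
  for (t in seq_len(T_ - 1L)) {
    m <- delta + lT  # K x K: from-state rows
    best <- apply(m, 2, which.max)
    delta <- m[cbind(best, seq_len(K))] + lB[t + 1L, ]
    psi[t + 1L, ] <- best
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  for (t in seq(T_ - 1L, length.out = T_ - 1L, by = -1L))
    path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

#' Assign biological labels to HMM states from their emission rows
#'
#' Rule table on emission probabilities, evaluated in order with the mark
#' order (ATAC, H3K4me3, H3K27ac): H3K4me3 high (>= 0.5) with H3K27ac high
#' gives TssA, H3K4me3 high alone TssW; H3K27ac high with ATAC high (and
#' H3K4me3 low) EnhA; H3K27ac moderate (0.2-0.5) EnhAW; ATAC high alone
#' ATAC_Is; everything low Quies. When two states claim the same label the
#' one with the larger emission margin keeps it and the other falls through
#' to its next applicable rule, with a warning.
#'
#' @param model trained `bernoulli_hmm` with K = 6 and marks in the order
#'   ATAC, H3K4me3, H3K27ac
#' @param high,moderate emission thresholds for "high" and "moderate"
#' @return character vector of labels, one per state
#' @export
label_states <- function(model, high = 0.5, moderate = 0.2) {
  E <- model$emissions
  if (nrow(E) != 6) stopf("label_states expects a 6-state model")
  atac <- E[, 1]; k4 <- E[, 2]; k27 <- E[, 3]
  # candidate (label, margin) lists per state, in rule order
  cand <- lapply(seq_len(nrow(E)), function(k) {
    out <- list()
    if (k4[k] >= high && k27[k] >= high)
      out <- c(out, list(c("TssA", min(k4[k], k27[k]) - high)))
    if (k4[k] >= high)
      out <- c(out, list(c("TssW", k4[k] - high)))
    if (k4[k] < high && k27[k] >= high && atac[k] >= high)
      out <- c(out, list(c("EnhA", min(atac[k], k27[k]) - high)))
    if (k27[k] >= moderate && k27[k] < high)
      out <- c(out, list(c("EnhAW", k27[k] - moderate)))
    if (atac[k] >= high && k4[k] < high && k27[k] < moderate)
      out <- c(out, list(c("ATAC_Is", atac[k] - high)))
    out <- c(out, list(c("Quies", high - max(atac[k], k4[k], k27[k]))))
    out
  })
  labels <- rep(NA_character_, nrow(E))
  taken <- character(0)
  # greedy assignment by margin, demoting collisions to the next rule
  repeat {
    todo <- which(is.na(labels))
    if (!length(todo)) break
    picks <- lapply(todo, function(k) {
      for (c_ in cand[[k]]) if (!(c_[1] %in% taken)) return(c_)
      c("Quies", "-1")
    })
    margins <- vapply(picks, function(p) as.numeric(p[2]), 0)
    want <- vapply(picks, `[`, "", 1)
    for (lab in unique(want)) {
      idx <- todo[want == lab]
      if (length(idx) > 1 && lab != "Quies") {
        warnf("states %s both map to %s; resolving by emission margin",
              paste(idx, collapse = ","), lab)
        keep <- idx[which.max(margins[match(idx, todo)])]
        labels[keep] <- lab
        taken <- c(taken, lab)
      } else {
        labels[idx[1]] <- lab
        if (lab != "Quies") taken <- c(taken, lab)
        if (lab == "Quies" && length(idx) > 1) labels[idx] <- "Quies"
      }
    }
  }
  names(labels) <- rownames(E)
  labels
}

#' Apply state labels to a segmentation
#' @param seg `segmentation` object
#' @param labels character vector from [label_states()]
#' @return the segmentation with `labels` set and labelled intervals
#' @export
apply_state_labels <- function(seg, labels) {
  seg$labels <- labels
  seg$intervals$label <- labels[seg$intervals$state]
  seg
}

#' Genome fraction covered by each state
#'
#' @param seg `segmentation` object
#' @return named numeric vector of fractions summing to 1
#' @export
state_coverage <- function(seg) {
  all_states <- unlist(seg$states, use.names = FALSE)
  tab <- table(factor(all_states, levels = sort(unique(all_states))))
  frac <- as.numeric(tab) / length(all_states)
  names(frac) <- if (!is.null(seg$labels))
    seg$labels[as.integer(names(tab))] else paste0("S", names(tab))
  frac
}

#' Interval set for one state of a segmentation
#' @param seg `segmentation`
#' @param state integer state id or character label (requires labels)
#' @return `genomic_intervals` data frame
#' @export
state_intervals <- function(seg, state) {
  iv <- seg$intervals
  keep <- if (is.character(state)) {
    if (is.null(iv$label)) stopf("segmentation has no labels; pass a state id")
    iv$label == state
  } else iv$state == state
  validate_intervals(iv[keep, c("chrom", "start", "end"), drop = FALSE])
}

#' Binary indicator track for one state
#' @param seg `segmentation`
#' @param state integer state id or character label
#' @return a [signal_track()] of 0/1 values on the segmentation bin grid
#' @export
state_indicator_track <- function(seg, state) {
  ids <- if (is.character(state)) which(seg$labels == state) else state
  signal_track(lapply(seg$states, function(s) as.numeric(s %in% ids)),
               seg$bin_size)
}

#' Strand-aware average profile around transcription start sites
#'
#' Windows of `2*flank` bp centered on each gene's TSS are aligned (reversed
#' for "-"-strand genes) and averaged per offset.
#'
#' @param track a [signal_track()] whose bin size equals `bin`
#' @param genes gene-model data frame (see [read_gene_models()])
#' @param flank half-window in bp, a multiple of `bin`
#' @param bin profile bin width in bp
#' @return data frame with `offset` (bp relative to TSS, bin midpoint
#'   convention: offset 0 is the TSS-containing bin) and `mean`
#' @export
tss_profile <- function(track, genes, flank = 2000, bin = 200) {
  stopifnot(inherits(track, "signal_track"))
  if (flank %% bin != 0) stopf("flank must be a multiple of bin")
  if (track$bin_size != bin)
    stopf("track bin size (%d) must equal profile bin (%d)", track$bin_size, bin)
  offs <- seq(-flank, flank, by = bin)
  n_off <- length(offs)
  acc <- numeric(n_off); cnt <- numeric(n_off)
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) next
    tss_bin <- ((genes$tss[i] - 1L) %/% bin) + 1L
    idx <- tss_bin + offs %/% bin
    ok <- idx >= 1 & idx <= length(v)
    vals <- rep(NA_real_, n_off)
    vals[ok] <- v[idx[ok]]
    if (genes$strand[i] == "-") vals <- rev(vals)
    use <- !is.na(vals)
    acc[use] <- acc[use] + vals[use]
    cnt[use] <- cnt[use] + 1
  }
  data.frame(offset = offs, mean = ifelse(cnt > 0, acc / cnt, NA_real_))
}

#' Merge per-tissue state intervals into a nonredundant set
#'
#' Union across tissues with overlapping or book-ended intervals merged
#' (the bedtools merge convention).
#'
#' @param sets list of interval data frames (one per tissue, same state)
#' @return merged `genomic_intervals` data frame
#' @export
merge_nonredundant <- function(sets) {
  sets <- Filter(function(s) nrow(s) > 0, sets)
  if (!length(sets)) return(genomic_intervals(character(0), integer(0), integer(0)))
  all_iv <- do.call(rbind, lapply(sets, function(s)
    s[, c("chrom", "start", "end"), drop = FALSE]))
  gr <- GenomicRanges::reduce(intervals_to_granges(validate_intervals(all_iv)))
  granges_to_intervals(gr)
}

#' Tissue presence matrix over a nonredundant element set
#'
#' An element is present in a tissue iff it overlaps that tissue's interval
#' set by at least 1 bp. Elements present in exactly one tissue are
#' tissue-specific (assigned to that tissue); elements present in all
#' tissues are common; the rest are shared.
#'
#' @param nonredundant nonredundant interval set (rows are elements)
#' @param tissue_sets named list of per-tissue interval data frames
#' @return list with `presence` (elements x tissues 0/1 matrix) and
#'   `elements` (intervals with `n_tissues`, `category`, `tissue` columns)
#' @export
call_tissue_specific <- function(nonredundant, tissue_sets) {
  stopifnot(length(tissue_sets) >= 2, !is.null(names(tissue_sets)))
  nr <- validate_intervals(nonredundant)
  gr_nr <- intervals_to_granges(nr)
  presence <- vapply(tissue_sets, function(s) {
    if (!nrow(s)) return(integer(length(gr_nr)))
    as.integer(IRanges::overlapsAny(gr_nr, intervals_to_granges(s)))
  }, integer(length(gr_nr)))
  if (is.null(dim(presence)))
    presence <- matrix(presence, nrow = length(gr_nr),
                       dimnames = list(NULL, names(tissue_sets)))
  n_t <- rowSums(presence)
  category <- ifelse(n_t == 1, "specific",
                     ifelse(n_t == length(tissue_sets), "common", "shared"))
  tissue <- rep(NA_character_, nrow(nr))
  spec <- which(n_t == 1)
  if (length(spec))
    tissue[spec] <- colnames(presence)[max.col(presence[spec, , drop = FALSE])]
  el <- nr
  el$n_tissues <- n_t
  el$category <- category
  el$tissue <- tissue
  list(presence = presence, elements = el)
}

#' Chromatin-state variability curve
#'
#' Cumulative fraction f(k) of nonredundant base pairs present in at most k
#' tissues, and the smallest k with f(k) >= 0.75 as a per-state variability
#' summary (small k = variable across tissues, k = n_tissues = constitutive).
#'
#' @param elements element table from [call_tissue_specific()] (needs
#'   `start`, `end`, `n_tissues`)
#' @param n_tissues total number of tissues
#' @return list with `k`, `f` (cumulative bp fraction) and `summary_k`
#' @export
variability_curve <- function(elements, n_tissues) {
  w <- elements$end - elements$start
  tot <- sum(w)
  f <- vapply(seq_len(n_tissues), function(k)
    sum(w[elements$n_tissues <= k]) / tot, 0)
  list(k = seq_len(n_tissues), f = f,
       summary_k = min(which(f >= 0.75)))
}
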