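# De novo motif discovery: ZOOPS (zero-or-one-occurrence-per-sequence)
# expectation-maximization over position weight matrices, searching both
# strands, with BIC-based width selection. This mirrors the classic
# EM-based motif-discovery configuration used for bacterial operator
# sites: motif width 6-20, at most one site per upstream sequence, 0-order
# background estimated from the input set.

#' Compile the upstream-region sequence set for motif discovery
#'
#' One sequence per distinct operon containing at least one target gene
#' (deduplicated: two targets in one operon contribute a single sequence),
#' taken as the `window` bp 5' of the operon leader on the coding strand
#' and truncated at contig edges.
#'
#' @param g genome object.
#' @param targets locus_tags of the genes of interest (e.g. predicted
#'   cellulases and beta-glucosidases).
#' @param window upstream window in bp (default 300).
#' @param gap_threshold operon gap rule in bp (default 100).
#' @return named character vector of sequences (names = leader locus_tags),
#'   with attribute `"provenance"` giving the operon ids.
#' @export
compile_upstream_set <- function(g, targets, window = 300,
                                 gap_threshold = 100) {
  unknown <- setdiff(targets, g$genes$locus_tag)
  if (length(unknown))
    stop("unknown locus_tag(s): ", paste(unknown, collapse = ", "))
  ops <- build_operons(g, gap_threshold)
  op_ids <- unique(ops$genes$operon_id[ops$genes$locus_tag %in% targets])
  seqs <- character(0); prov <- character(0)
  for (oid in op_ids) {
    op <- ops$operons[ops$operons$operon_id == oid, ]
    reg <- upstream_region(op, g, window)
    if (reg$end <= reg$start) next
    s <- substr(g$contigs[[reg$contig_id]], reg$start + 1L, reg$end)
    if (reg$strand == "-") s <- revcomp(s)
    seqs <- c(seqs, setNames(s, op$leader))
    prov <- c(prov, oid)
  }
  attr(seqs, "provenance") <- prov
  seqs
}

# One-hot window matrix for one width: rows are (sequence, strand, offset)
# windows on both strands, columns are 4*w indicators. Returns the matrix
# plus the row bookkeeping needed for per-sequence normalization.
build_window_matrix <- function(seqs, w) {
  rows <- list(); seq_of_row <- integer(0)
  meta <- list()
  for (s in seq_along(seqs)) {
    for (strand in c("+", "-")) {
      x <- if (strand == "+") seqs[[s]] else revcomp(seqs[[s]])
      code <- encode_dna(x)
      L <- length(code); m <- L - w + 1
      if (m < 1) next
      # windows x w matrix of base codes
      wm <- vapply(seq_len(w), function(k) code[k:(k + m - 1)], integer(m))
      if (m == 1) wm <- matrix(wm, nrow = 1)
      rows[[length(rows) + 1]] <- wm
      seq_of_row <- c(seq_of_row, rep(s, m))
      meta[[length(meta) + 1]] <- data.frame(
        seq = s, strand = strand, pos = seq_len(m) - 1L)
    }
  }
  codes <- do.call(rbind, rows)
  n <- nrow(codes)
  X <- matrix(0, nrow = n, ncol = 4L * w)
  valid <- codes >= 1 & codes <= 4
  for (k in seq_len(w)) {
    ok <- valid[, k]
    X[cbind(which(ok), (k - 1L) * 4L + codes[ok, k])] <- 1
  }
  list(X = X, seq_of_row = seq_of_row, meta = do.call(rbind, meta))
}

# 0-order background from both strands of the input set.
background_freqs <- function(seqs) {
  counts <- setNames(numeric(4), DNA_BASES)
  for (s in seqs) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    tb <- table(factor(chars, levels = DNA_BASES))
    counts <- counts + tb
  }
  counts <- counts + rev(counts)          # strand symmetry: A<->T, C<->G
  p <- counts / sum(counts)
  pmax(p, 1e-6) / sum(pmax(p, 1e-6))
}

# Run ZOOPS EM from one initialization. Returns pwm (w x 4), gamma, the
# final data log-likelihood, the EM objective trace and responsibilities.
# The M-step uses a 0.25 pseudocount per base, i.e. a Dirichlet(1.25)
# prior on PWM columns, so the quantity EM provably never decreases is
# the penalized (MAP) objective: data log-likelihood + 0.25*sum(log p).
# That objective is what `trace` records; `logL` is the data term alone.
zoops_em <- function(wm, w, bg, init_probs, gamma0 = 0.75,
                     tol = 1e-6, max_iter = 500) {
  X <- wm$X
  seq_of <- wm$seq_of_row
  n_seq <- max(seq_of)
  m2 <- tabulate(seq_of, n_seq)           # windows per sequence, both strands
  log_bg_rep <- rep(log(bg), w)
  probs <- init_probs
  gamma <- gamma0
  trace <- numeric(0)
  z <- NULL
  for (iter in seq_len(max_iter)) {
    theta <- as.vector(t(log(probs))) - log_bg_rep   # row-major w x 4
    lr <- as.vector(X %*% theta)                     # log likelihood ratios
    r <- exp(lr)
    sum_r <- as.vector(rowsum(r, seq_of))
    denom <- (1 - gamma) + gamma * sum_r / m2
    z <- (gamma / m2[seq_of]) * r / denom[seq_of]
    q <- gamma * (sum_r / m2) / denom                # presence posterior
    ll <- sum(log(denom))                            # up to the constant bg term
    trace <- c(trace, ll + 0.25 * sum(log(probs)))   # MAP objective
    # M-step
    cnt <- as.vector(crossprod(X, z)) + 0.25
    pm <- matrix(cnt, nrow = w, byrow = TRUE)
    probs_new <- pm / rowSums(pm)
    gamma_new <- min(max(mean(q), 1e-4), 1)
    if (iter > 1 && abs(trace[iter] - trace[iter - 1]) < tol) {
      probs <- probs_new; gamma <- gamma_new
      break
    }
    probs <- probs_new; gamma <- gamma_new
  }
  list(probs = probs, gamma = gamma, logL = ll, trace = trace, z = z)
}

# Seed a PWM from one window of the input (row index into wm$X).
seed_pwm <- function(wm, w, bg, i = sample.int(nrow(wm$X), 1)) {
  onehot <- matrix(wm$X[i, ], nrow = w, byrow = TRUE)
  probs <- 0.45 * matrix(bg, nrow = w, ncol = 4, byrow = TRUE) + 0.55 * onehot
  # windows containing N have zero rows; fall back to background there
  zero <- rowSums(onehot) == 0
  if (any(zero))
    probs[zero, ] <- matrix(bg, nrow = sum(zero), ncol = 4, byrow = TRUE)
  probs / rowSums(probs)
}

# Shift a PWM left (s < 0) or right (s > 0), filling vacated rows with
# the background distribution. Used for phase refinement: EM can converge
# to an alignment off by one or two columns from the optimum.
shift_pwm <- function(probs, s, bg) {
  w <- nrow(probs)
  out <- matrix(bg, nrow = w, ncol = 4, byrow = TRUE)
  if (s >= 0) {
    keep <- seq_len(w - s)
    out[keep, ] <- probs[keep + s, ]
  } else {
    keep <- seq_len(w + s)
    out[keep - s, ] <- probs[keep, ]
  }
  out
}

# ZOOPS observed-data log-likelihood (up to the constant background term)
# of a fixed PWM -- used to pre-screen candidate seeds cheaply.
zoops_loglik <- function(wm, w, bg, probs, gamma = 0.75) {
  seq_of <- wm$seq_of_row
  m2 <- tabulate(seq_of, max(seq_of))
  theta <- as.vector(t(log(probs))) - rep(log(bg), w)
  r <- exp(as.vector(wm$X %*% theta))
  sum_r <- as.vector(rowsum(r, seq_of))
  sum(log((1 - gamma) + gamma * sum_r / m2))
}

#' Discover one motif in a set of upstream sequences (ZOOPS EM)
#'
#' For every candidate width, EM starts are seeded from randomly chosen
#' input subsequences: `n_starts` candidate seeds are pre-screened by
#' their one-step ZOOPS likelihood, the best few are advanced a few EM
#' iterations, and the best of those is run to convergence
#' (log-likelihood change below `tol`, or 500 iterations). Both strands
#' of every sequence are considered; the E-step computes the posterior
#' over site positions and site presence per sequence under the ZOOPS
#' likelihood with a 0-order background, and the M-step re-estimates the
#' PWM (pseudocount 0.25 per base) and the site prior. The best model
#' across widths is selected by a BIC-penalized log-likelihood with
#' 3 x width free parameters, the observation count being the expected
#' number of sites under the fitted site prior. Deterministic given
#' `seed`.
#'
#' @param seqs named character vector of DNA sequences (e.g. from
#'   [compile_upstream_set()]); at least 2.
#' @param width_range integer `c(min, max)` motif width (default
#'   `c(6, 20)`).
#' @param n_starts subsequence-seeded initializations screened per width
#'   (default 40).
#' @param seed RNG seed.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @return list of class `motif_model`: `pwm` (list: `width`, `probs`
#'   (width x 4, columns A/C/G/T), `site_prior`, `background`),
#'   `consensus` (per-column argmax string), `logL` (data log-likelihood
#'   up to the constant background term), `logL_trace` (the EM objective
#'   -- the Dirichlet-penalized log-likelihood the M-step maximizes --
#'   monotone non-decreasing), `bic_score`, `posteriors` (per sequence:
#'   `name`, `presence`, `best_pos` 0-based, `best_strand`), and
#'   `width_scores` for all candidate widths.
#' @export
discover_motif <- function(seqs, width_range = c(6, 20), n_starts = 40,
                           seed = 1, tol = 1e-6) {
  stopifnot(length(seqs) >= 2)
  widths <- seq(width_range[1], width_range[2])
  max_len <- max(nchar(seqs))
  widths <- widths[widths <= max_len]
  if (!length(widths))
    stop("all sequences are shorter than the minimum motif width")
  bg <- background_freqs(seqs)
  n_seq <- length(seqs)
  with_local_seed(seed, {
    best <- NULL; width_scores <- list(); prev_fit <- NULL
    for (w in widths) {
      wm <- build_window_matrix(seqs, w)
      if (is.null(wm$X) || nrow(wm$X) < 1) next
      n_win <- nrow(wm$X)
      # screen subsequence seeds by one-step likelihood, refine the best
      cand <- sample.int(n_win, min(n_starts, n_win))
      seed_ll <- vapply(cand, function(i)
        zoops_loglik(wm, w, bg, seed_pwm(wm, w, bg, i)), numeric(1))
      top_idx <- cand[order(seed_ll, decreasing = TRUE)[
        seq_len(min(4, length(cand)))]]
      starts <- lapply(top_idx, function(i) {
        zoops_em(wm, w, bg, seed_pwm(wm, w, bg, i), tol = tol,
                 max_iter = 20)
      })
      # cross-width seeding: extend the previous width's converged PWM by
      # a background column on either side -- guards against a width
      # getting stuck in a worse optimum than its neighbours
      if (!is.null(prev_fit) && nrow(prev_fit$probs) == w - 1) {
        bg_row <- matrix(bg, nrow = 1)
        for (p in list(rbind(prev_fit$probs, bg_row),
                       rbind(bg_row, prev_fit$probs))) {
          starts[[length(starts) + 1]] <-
            zoops_em(wm, w, bg, p, gamma0 = prev_fit$gamma, tol = tol,
                     max_iter = 20)
        }
      }
      top <- starts[[which.max(vapply(starts, `[[`, numeric(1), "logL"))]]
      fit <- zoops_em(wm, w, bg, top$probs, gamma0 = top$gamma,
                      tol = tol, max_iter = 500)
      fit$trace <- c(top$trace, fit$trace)
      # phase refinement: try +/-1, +/-2 column shifts of the converged
      # PWM and keep the best re-converged model
      for (s in c(-2L, -1L, 1L, 2L)) {
        f <- zoops_em(wm, w, bg, shift_pwm(fit$probs, s, bg),
                      gamma0 = fit$gamma, tol = tol, max_iter = 40)
        if (f$logL > fit$logL + 1e-9) {
          fit <- zoops_em(wm, w, bg, f$probs, gamma0 = f$gamma,
                          tol = tol, max_iter = 500)
          fit$trace <- c(f$trace, fit$trace)
        }
      }
      # Penalized width selection. BIC alone (3w free parameters over the
      # ~gamma*n_seq site-bearing sequences) under-penalizes width here:
      # with a palindromic core the two-strand ZOOPS alignment lets every
      # site present its better-fitting flank to an added edge column, a
      # selection gain that grows with the site count. The per-column
      # penalty is therefore floored at 0.55 nats per expected site --
      # above that strand-choice gain, below the contribution of any
      # genuinely conserved column (a two-base degenerate column is worth
      # log(2) = 0.69 nats per site).
      n_obs <- max(fit$gamma * n_seq, 2)
      per_col <- max(1.5 * log(n_obs), 0.55 * n_obs)
      score <- fit$logL - w * per_col
      width_scores[[as.character(w)]] <- score
      prev_fit <- fit
      if (is.null(best) || score > best$score)
        best <- list(w = w, fit = fit, wm = wm, score = score)
    }
    w <- best$w; fit <- best$fit; wm <- best$wm
    # Trim uninformative flanking columns from the selected model. With a
    # palindromic core, the two-strand ZOOPS alignment lets every
    # sequence present its better-fitting flank base to an added edge
    # column, which inflates the likelihood gain of widening past the
    # true motif; edge columns below 0.5 bits of information content are
    # therefore trimmed and the model re-converged at the reduced width.
    col_ic <- function(p) vapply(seq_len(nrow(p)), function(i)
      sum(p[i, ] * log2(pmax(p[i, ], 1e-12) / bg)), numeric(1))
    repeat {
      if (w <= width_range[1]) break
      ic <- col_ic(fit$probs)
      if (ic[1] < 0.5) {
        fit$probs <- fit$probs[-1, , drop = FALSE]; w <- w - 1L
      } else if (ic[w] < 0.5) {
        fit$probs <- fit$probs[-w, , drop = FALSE]; w <- w - 1L
      } else break
    }
    if (w != best$w) {
      wm <- build_window_matrix(seqs, w)
      fit <- zoops_em(wm, w, bg, fit$probs, gamma0 = fit$gamma,
                      tol = tol, max_iter = 200)
    }
    colnames(fit$probs) <- DNA_BASES
    consensus <- paste(DNA_BASES[max.col(fit$probs, ties.method = "first")],
                       collapse = "")
    # per-sequence presence posterior and best site
    post <- do.call(rbind, lapply(seq_len(n_seq), function(s) {
      idx <- which(wm$seq_of_row == s)
      if (!length(idx))
        return(data.frame(name = names(seqs)[s], presence = 0,
                          best_pos = NA_integer_, best_strand = NA_character_))
      zi <- fit$z[idx]
      b <- idx[which.max(zi)]
      data.frame(name = names(seqs)[s] %||% as.character(s),
                 presence = sum(zi),
                 best_pos = wm$meta$pos[b],
                 best_strand = wm$meta$strand[b],
                 stringsAsFactors = FALSE)
    }))
    structure(list(
      pwm = list(width = w, probs = fit$probs, site_prior = fit$gamma,
                 background = bg),
      consensus = consensus,
      logL = fit$logL,
      logL_trace = fit$trace,
      bic_score = best$score,
      posteriors = post,
      width_scores = unlist(width_scores)),
      class = "motif_model")
  })
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> width=%d  site_prior=%.2f  argmax %s\n",
              x$pwm$width, x$pwm$site_prior, x$consensus))
  invisible(x)
}

#' Convert a PWM to a degenerate consensus
#'
#' Position i's allowed set contains every base whose probability is at
#' least `threshold`; the per-column argmax base is always included, so
#' the set is never empty. This bridges discovered PWMs to the
#' "(A/T)"-style degenerate site notation used by the scanner.
#'
#' @param p PWM list as in a [discover_motif()] result (`$pwm`), or a
#'   width x 4 probability matrix with columns A/C/G/T.
#' @param threshold inclusion threshold (default 0.25).
#' @param consensus_id identifier for the resulting pattern.
#' @return a [degenerate_consensus()].
#' @export
pwm_to_consensus <- function(p, threshold = 0.25,
                             consensus_id = "discovered") {
  probs <- if (is.list(p) && !is.null(p$probs)) p$probs else p
  stopifnot(is.matrix(probs), ncol(probs) == 4)
  positions <- lapply(seq_len(nrow(probs)), function(i) {
    allowed <- DNA_BASES[probs[i, ] >= threshold]
    union(allowed, DNA_BASES[which.max(probs[i, ])])
  })
  degenerate_consensus(positions, consensus_id)
}
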