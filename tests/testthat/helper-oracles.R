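# Independent oracles used across the test suite. These deliberately use
# naive, readable algorithms (explicit physical states, dense matrices,
# linear scans) so they share no code path with the implementation.

# Brute-force physical-state HMM: tracks the exact per-position fluorophore
# booleans (which residue still carries which dye) instead of reduced counts.
# States: (r = residues removed, mask over labeled positions) + DETACHED.
physical_forward <- function(code, params, y) {
  chars <- strsplit(code, "")[[1]]
  chan <- match(chars, fluorseq:::channel_chars)
  pos <- which(!is.na(chan))
  pchan <- chan[pos]
  L <- length(pos)
  len <- length(chars)
  Tn <- params$n_timesteps
  rmax <- min(len, Tn - 1L)
  states <- list()
  for (r in 0:rmax) {
    alive <- pos[pos > r]                # dyes on removed residues are gone
    masks <- if (length(alive) == 0) list(integer(0)) else {
      unlist(lapply(0:(2^length(alive) - 1), function(b) {
        list(alive[bitwAnd(b, 2^(seq_along(alive) - 1)) > 0])
      }), recursive = FALSE)
    }
    for (mk in masks) states[[length(states) + 1L]] <- list(r = r, mask = mk)
  }
  states[[length(states) + 1L]] <- list(r = -1L, mask = integer(0)) # DETACHED
  ns <- length(states)
  key <- vapply(states, function(s) paste(s$r, paste(s$mask, collapse = ","),
                                          sep = "|"), character(1))
  idx <- setNames(seq_len(ns), key)
  kf <- function(r, mask) idx[[paste(r, paste(sort(mask), collapse = ","),
                                     sep = "|")]]
  # initial distribution: duds only
  init <- numeric(ns)
  for (b in 0:(2^L - 1)) {
    mask <- pos[bitwAnd(b, 2^(seq_len(L) - 1)) > 0]
    pr <- 1
    for (j in seq_len(L)) {
      mc <- params$m[pchan[j]]
      pr <- pr * if (pos[j] %in% mask) (1 - mc) else mc
    }
    init[kf(0L, mask)] <- init[kf(0L, mask)] + pr
  }
  # one-step transition: detach, then Edman, then per-dye bleach
  M <- matrix(0, ns, ns)
  for (j in seq_len(ns)) {
    s <- states[[j]]
    if (s$r < 0) { M[j, j] <- 1; next }
    M[kf(-1L, integer(0)), j] <- M[kf(-1L, integer(0)), j] + params$d
    # after surviving detachment: Edman branch
    branches <- if (s$r >= rmax) list(list(p = 1, r = s$r, mask = s$mask)) else {
      list(list(p = params$e, r = s$r, mask = s$mask),
           list(p = 1 - params$e, r = s$r + 1L,
                mask = setdiff(s$mask, s$r + 1L)))
    }
    for (br in branches) {
      mk <- br$mask
      nbits <- length(mk)
      for (b in 0:(2^max(nbits, 1) - 1)) {
        if (nbits == 0 && b > 0) break
        keep <- if (nbits == 0) integer(0) else
          mk[bitwAnd(b, 2^(seq_len(nbits) - 1)) > 0]
        pr <- 1
        for (q in mk) {
          pc <- params$p[pchan[match(q, pos)]]
          pr <- pr * if (q %in% keep) (1 - pc) else pc
        }
        tgt <- kf(br$r, keep)
        M[tgt, j] <- M[tgt, j] + (1 - params$d) * br$p * pr
      }
    }
  }
  emis <- function(t) {
    vapply(states, function(s) {
      w <- 1
      for (ch in seq_len(params$n_channels)) {
        lc <- sum(pchan[match(s$mask, pos)] == ch)
        w <- w * dnorm(y[t, ch], lc * params$mu[ch],
                       sqrt(params$sigma_bg[ch]^2 + lc * params$sigma[ch]^2))
      }
      w
    }, numeric(1))
  }
  f <- init * emis(1)
  if (Tn > 1) for (t in 2:Tn) f <- (M %*% f)[, 1] * emis(t)
  sum(f)
}

# Dense one-step transition matrix built by direct compound enumeration
# (detach, then Edman, then independent per-channel binomial dye loss),
# without going through the sparse factor constructors.
dense_transition_oracle <- function(space, params) {
  ns <- space$n_states
  C <- ncol(space$ell)
  chars <- strsplit(space$code, "")[[1]]
  chan_at <- match(chars, fluorseq:::channel_chars)
  M <- matrix(0, ns, ns)
  M[space$detached, space$detached] <- 1
  for (j in seq_len(ns - 1L)) {
    e <- space$estar[j]
    l <- space$ell[j, ]
    M[space$detached, j] <- M[space$detached, j] + params$d
    branches <- if (e >= space$e_max) {
      list(list(p = 1, e = e, l = l))
    } else {
      ch <- chan_at[e + 1L]
      adv <- if (is.na(ch)) {
        list(list(p = 1 - params$e, e = e + 1L, l = l))
      } else {
        n_now <- space$n_after[e + 1L, ch]
        lr <- l; lr[ch] <- lr[ch] - 1L
        out <- list()
        if (l[ch] > 0) {
          out <- c(out, list(list(p = (1 - params$e) * l[ch] / n_now,
                                  e = e + 1L, l = lr)))
        }
        if (l[ch] < n_now) {
          out <- c(out, list(list(p = (1 - params$e) * (1 - l[ch] / n_now),
                                  e = e + 1L, l = l)))
        }
        out
      }
      c(list(list(p = params$e, e = e, l = l)), adv)
    }
    for (br in branches) {
      if (br$p == 0) next
      # enumerate all joint bleaching outcomes
      grids <- lapply(seq_len(C), function(ch) 0:br$l[ch])
      targets <- as.matrix(expand.grid(grids))
      for (r in seq_len(nrow(targets))) {
        pr <- br$p
        for (ch in seq_len(C)) {
          pr <- pr * dbinom(targets[r, ch], br$l[ch], 1 - params$p[ch])
        }
        i <- space$index_of(br$e, targets[r, ])
        M[i, j] <- M[i, j] + (1 - params$d) * pr
      }
    }
  }
  M
}

# Linear-scan exact kNN oracle: returns entries and distances sorted by
# (distance, entry id).
linear_knn <- function(points, query, k) {
  d <- sqrt(colSums((t(points) - query)^2))
  ord <- order(d, seq_along(d))
  ord <- ord[seq_len(min(k, length(d)))]
  list(entry = ord, dist = d[ord])
}

# Brute-force PR curve by explicit threshold enumeration.
brute_pr <- function(score, correct, n_total = length(score)) {
  th <- sort(unique(score), decreasing = TRUE)
  data.frame(threshold = th,
             recall = vapply(th, function(s) {
               sum(correct[score >= s]) / n_total
             }, numeric(1)),
             precision = vapply(th, function(s) {
               sum(correct[score >= s]) / sum(score >= s)
             }, numeric(1)))
}

# Small random dye-seq codes for property tests.
random_code <- function(max_len = 5, max_labels = 3, n_channels = 2) {
  repeat {
    len <- sample(1:max_len, 1)
    n_lab <- sample(1:min(max_labels, len), 1)
    code <- rep(".", len)
    code[sample(len, n_lab)] <- as.character(sample(0:(n_channels - 1),
                                                    n_lab, replace = TRUE))
    code <- sub("\\.+$", "", paste(code, collapse = ""))
    if (nzchar(code)) return(code)
  }
}

# Default-scheme reference built from a small synthetic proteome.
tiny_reference <- function(n_proteins = 20, seed = 42, mean_length = 300,
                           scheme = make_label_scheme("trypsin",
                                                      c("DE", "C", "Y"))) {
  prots <- random_proteome(n_proteins, mean_length = mean_length, seed = seed)
  make_dye_seqs(prots, scheme)
}
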