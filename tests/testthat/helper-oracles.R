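# Independent oracles: naive term-enumeration energy evaluation, exhaustive
# structure enumeration for partition-function checks, and brute-force
# enumeration of monotone duplex pairings. Deliberately separate
# implementations from the package's recursions.

.ORACLE_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

oracle_pt <- function(a, b) match(paste0(a, b), .ORACLE_PAIRS)

oracle_au <- function(params, t) {
  if (t %in% c(1, 2, 5, 6)) params$terminal_au else 0
}

oracle_looptab <- function(params, tab, len) {
  v <- params[[tab]]
  if (len <= length(v)) v[len] else v[length(v)] + params$lxc * log(len / length(v))
}

# lists every stack/loop term of a structure and sums them
oracle_structure_energy <- function(seq_chars, pairs, params) {
  n <- length(seq_chars)
  mate <- integer(n)
  if (nrow(pairs) > 0) {
    mate[pairs[, 1]] <- pairs[, 2]
    mate[pairs[, 2]] <- pairs[, 1]
  }
  children <- function(i, j) {
    out <- list()
    k <- i + 1
    while (k < j) {
      if (k >= 1 && k <= n && mate[k] > k) {
        out[[length(out) + 1]] <- c(k, mate[k])
        k <- mate[k] + 1
      } else {
        k <- k + 1
      }
    }
    out
  }
  total <- 0
  todo <- children(0, n + 1)
  for (b in todo) {
    total <- total + oracle_au(params, oracle_pt(seq_chars[b[1]], seq_chars[b[2]]))
  }
  while (length(todo) > 0) {
    b <- todo[[1]]
    todo <- todo[-1]
    i <- b[1]; j <- b[2]
    t <- oracle_pt(seq_chars[i], seq_chars[j])
    ch <- children(i, j)
    if (length(ch) == 0) {
      total <- total + oracle_looptab(params, "hairpin", j - i - 1) +
        oracle_au(params, t)
    } else if (length(ch) == 1) {
      k <- ch[[1]][1]; l <- ch[[1]][2]
      g1 <- k - i - 1; g2 <- j - l - 1
      t2 <- oracle_pt(seq_chars[k], seq_chars[l])
      if (g1 == 0 && g2 == 0) {
        total <- total + params$stack[t, t2]
      } else if (g1 == 0 || g2 == 0) {
        total <- total + oracle_looptab(params, "bulge", g1 + g2) +
          oracle_au(params, t) + oracle_au(params, t2)
      } else {
        total <- total + oracle_looptab(params, "internal", g1 + g2) +
          oracle_au(params, t) + oracle_au(params, t2)
      }
    } else {
      npaired <- sum(vapply(ch, function(x) x[2] - x[1] + 1, numeric(1)))
      total <- total + params$ml_close + oracle_au(params, t) +
        params$ml_unpaired * ((j - i - 1) - npaired)
      for (c2 in ch)
        total <- total + params$ml_branch +
          oracle_au(params, oracle_pt(seq_chars[c2[1]], seq_chars[c2[2]]))
    }
    todo <- c(todo, ch)
  }
  total
}

# all pseudoknot-free structures (hairpins >= 3, allowed pairs)
oracle_enumerate_structures <- function(seq_chars) {
  n <- length(seq_chars)
  pairable <- function(i, j) {
    j - i > 3 && !is.na(oracle_pt(seq_chars[i], seq_chars[j]))
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste0(i, "_", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1, j)
    if (i + 4 <= j) {
      for (k in (i + 4):j) {
        if (pairable(i, k)) {
          left <- rec(i + 1, k - 1)
          right <- rec(k + 1, j)
          for (a in left) for (b in right)
            out[[length(out) + 1]] <- rbind(matrix(c(i, k), ncol = 2), a, b)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

# exhaustive partition function, pair probabilities and structure weights
oracle_partition <- function(seq_chars, params) {
  structs <- oracle_enumerate_structures(seq_chars)
  energies <- vapply(structs, function(p) {
    oracle_structure_energy(seq_chars, p, params)
  }, numeric(1))
  w <- exp(-energies / params$rt)
  Z <- sum(w)
  n <- length(seq_chars)
  P <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    p <- structs[[k]]
    if (nrow(p) > 0) {
      P[p] <- P[p] + w[k]
      P[p[, c(2, 1), drop = FALSE]] <- P[p[, c(2, 1), drop = FALSE]] + w[k]
    }
  }
  list(structures = structs, energies = energies, weights = w, Z = Z,
       pair_prob = P / Z)
}

# brute-force minimum over every monotone antiparallel duplex pairing
oracle_best_duplex <- function(s_str, m_str, params, max_loop = 15) {
  s <- strsplit(s_str, "")[[1]]
  m <- strsplit(m_str, "")[[1]]
  ns <- length(s); nm <- length(m)
  allowed <- function(i, j) !is.na(oracle_pt(s[i], m[j]))
  best <- Inf
  best_pairs <- NULL
  rec <- function(pairs) {
    e <- duplex_energy(s_str, m_str, pairs, params)
    if (e < best) {
      best <<- e
      best_pairs <<- pairs
    }
    i <- pairs[nrow(pairs), 1]; j <- pairs[nrow(pairs), 2]
    if (i + 1 <= ns && j - 1 >= 1) {
      for (i2 in (i + 1):min(ns, i + 1 + max_loop)) {
        for (j2 in (j - 1):max(1, j - 1 - max_loop)) {
          if (allowed(i2, j2)) rec(rbind(pairs, c(i2, j2)))
        }
      }
    }
  }
  for (i in seq_len(ns)) for (j in seq_len(nm))
    if (allowed(i, j)) rec(matrix(c(i, j), ncol = 2))
  list(energy = best, pairs = best_pairs)
}

# deterministic pseudo-random sequences for fixtures
random_rna <- function(n, seed, alphabet = c("A", "C", "G", "U")) {
  x <- seed %% 2147483646 + 1
  out <- character(n)
  for (k in seq_len(n)) {
    x <- (x * 48271) %% 2147483647
    out[k] <- alphabet[(x %% length(alphabet)) + 1]
  }
  paste(out, collapse = "")
}

# structure_ensemble built directly from a list of structures (test scaffold)
manual_ensemble <- function(seq, structures, params = energy_params()) {
  seq <- if (inherits(seq, "rna_sequence")) seq else rna_sequence(seq)
  nn <- length(seq)
  counts <- matrix(0, nn, nn)
  for (st in structures) {
    p <- st$pairs
    if (nrow(p) > 0) {
      counts[p] <- counts[p] + 1
      counts[p[, c(2, 1), drop = FALSE]] <- counts[p[, c(2, 1), drop = FALSE]] + 1
    }
  }
  pair_prob <- counts / length(structures)
  structure(list(
    seq = seq, structures = structures,
    ensemble_energies = vapply(structures, function(st) {
      structure_energy(seq, st, params)
    }, numeric(1)),
    n = length(structures), seed = NA_integer_, pair_prob = pair_prob,
    ss_profile = 1 - rowSums(pair_prob)
  ), class = "structure_ensemble")
}
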