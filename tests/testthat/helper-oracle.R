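# Independent brute-force oracles for the texture engine and the statistics.
# These deliberately use naive enumeration (triple loops, explicit line
# walking, flood fill, rank arithmetic) so they share no code path with the
# package implementation.

# --- co-occurrence: explicit pair listing ---------------------------------
oracle_cm <- function(la, d) {
  dims <- dim(la)
  L <- max(la, na.rm = TRUE)
  M <- matrix(0, L, L)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    a <- la[i, j, k]
    if (is.na(a)) next
    ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
    if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] || kk < 1 || kk > dims[3]) next
    b <- la[ii, jj, kk]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

oracle_cm_indices <- function(la, directions, log_base = 2) {
  vals <- NULL
  for (k in seq_len(nrow(directions))) {
    P <- oracle_cm(la, directions[k, ])
    if (is.null(P)) next
    L <- nrow(P)
    hom <- ent <- con <- 0
    for (i in seq_len(L)) for (j in seq_len(L)) {
      p <- P[i, j]
      hom <- hom + p / (1 + abs(i - j))
      con <- con + p * (i - j)^2
      if (p > 0) ent <- ent - p * log(p, base = log_base)
    }
    vals <- rbind(vals, c(hom, ent, con))
  }
  colMeans(vals)
}

# --- run lengths: explicit line walking -----------------------------------
oracle_runs <- function(la, d) {
  dims <- dim(la)
  runs <- NULL
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    lev <- la[i, j, k]
    if (is.na(lev)) next
    p <- c(i, j, k) - d
    prev_same <- all(p >= 1) && all(p <= dims) &&
      !is.na(la[p[1], p[2], p[3]]) && la[p[1], p[2], p[3]] == lev
    if (prev_same) next                     # not a run start
    len <- 1L
    q <- c(i, j, k) + d
    while (all(q >= 1) && all(q <= dims) &&
           !is.na(la[q[1], q[2], q[3]]) && la[q[1], q[2], q[3]] == lev) {
      len <- len + 1L
      q <- q + d
    }
    runs <- rbind(runs, c(lev, len))
  }
  runs
}

oracle_grlm_matrix <- function(la, d) {
  runs <- oracle_runs(la, d)
  L <- max(la, na.rm = TRUE)
  G <- matrix(0, L, max(runs[, 2]))
  for (r in seq_len(nrow(runs))) G[runs[r, 1], runs[r, 2]] <- G[runs[r, 1], runs[r, 2]] + 1
  G
}

oracle_grlm_indices <- function(la, directions) {
  vals <- NULL
  for (k in seq_len(nrow(directions))) {
    runs <- oracle_runs(la, directions[k, ])
    H <- nrow(runs)
    sre <- sum(1 / runs[, 2]^2) / H
    lre <- sum(runs[, 2]^2) / H
    cnt <- table(runs[, 2])
    rlnu <- sum(as.numeric(cnt)^2) / H
    vals <- rbind(vals, c(sre, lre, rlnu))
  }
  colMeans(vals)
}

# --- zones: flood fill -----------------------------------------------------
oracle_zones <- function(la, connectivity = 26L) {
  dims <- dim(la)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1L, , drop = FALSE]
  seen <- array(FALSE, dims)
  zones <- NULL
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (is.na(la[i, j, k]) || seen[i, j, k]) next
    lev <- la[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (o in seq_len(nrow(off))) {
        q <- cur + off[o, ]
        if (any(q < 1) || any(q > dims)) next
        if (seen[q[1], q[2], q[3]] || is.na(la[q[1], q[2], q[3]])) next
        if (la[q[1], q[2], q[3]] != lev) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
    zones <- rbind(zones, c(lev, size))
  }
  zones
}

oracle_gzlm_matrix <- function(la, connectivity = 26L) {
  zones <- oracle_zones(la, connectivity)
  L <- max(la, na.rm = TRUE)
  Z <- matrix(0, L, max(zones[, 2]))
  for (r in seq_len(nrow(zones))) Z[zones[r, 1], zones[r, 2]] <- Z[zones[r, 1], zones[r, 2]] + 1
  Z
}

oracle_gzlm_indices <- function(la, connectivity = 26L) {
  zones <- oracle_zones(la, connectivity)
  H <- nrow(zones)
  c(sum(1 / zones[, 1]^2) / H, sum(zones[, 1]^2) / H)
}

# --- statistics oracles ----------------------------------------------------
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exact two-sided signed-rank p by enumerating every sign assignment.
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null_w <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  if (w > mu) {
    p <- 2 * mean(null_w >= w)
  } else {
    p <- 2 * mean(null_w <= w)
  }
  min(p, 1)
}

# Exact two-sided rank-sum p by enumerating every group assignment.
oracle_rank_sum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  null_u <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * n / 2
  if (u > mu) {
    p <- 2 * mean(null_u >= u)
  } else {
    p <- 2 * mean(null_u <= u)
  }
  min(p, 1)
}

# --- fixtures --------------------------------------------------------------
# Random small gray-level lattice with NA outside a random mask.
random_level_lattice <- function(dims = c(4, 4, 4), n_levels = 5,
                                 mask_prob = 0.6) {
  la <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  keep <- array(stats::runif(prod(dims)) < mask_prob, dims)
  if (sum(keep) < 2) keep[sample(prod(dims), 2)] <- TRUE
  la[!keep] <- NA_integer_
  la
}

# Wrap a gray-level lattice as (volume, mask) whose AR(D = max level, bounds
# chosen to make level k correspond to SUV k) reproduces exactly that lattice.
lattice_as_suv_volume <- function(la) {
  vals <- array(0, dim(la))
  vals[!is.na(la)] <- la[!is.na(la)]
  list(vol = volume_grid(vals, unit = "suv"),
       mask = voi_mask(!is.na(la)))
}
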