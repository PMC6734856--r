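# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: dense sampling instead of closed forms,
# exhaustive enumeration instead of Dijkstra, definitional loops instead of
# vectorized sums of squares, explicit replay instead of the session loop.

# shared small environment (jitter 0 keeps landmark positions closed-form)
fixture_env <- function(seed = 7, jitter = 2) {
  generate_environment(seed, env_params(jitter = jitter))
}

# --- dense-sampling distance to a polyline -------------------------------
oracle_polyline_distance <- function(p, line, ds = 0.01) {
  seg <- sqrt(rowSums((line[-1, , drop = FALSE] - line[-nrow(line), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  s <- c(seq(0, cum[length(cum)], by = ds), cum[length(cum)])
  pts <- cathtrain::centerline_point_at(line, s)
  min(sqrt(colSums((t(pts) - p)^2)))
}

# --- brute-force signed distance via dense surface sampling --------------
# magnitude from the nearest dense surface sample; sign from elementary
# vectorized R geometry (independent of the C++ closed forms)
oracle_min_dist_chunked <- function(queries, pts, chunk = 40) {
  out <- numeric(nrow(queries))
  tp <- t(pts)
  for (i0 in seq(1, nrow(queries), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1, nrow(queries))
    for (j in idx) out[j] <- sqrt(min(colSums((tp - queries[j, ])^2)))
  }
  out
}

oracle_sdf_sign <- function(p, organ) {
  r <- organ$row
  if (organ$shape == "sphere") {
    if (sum((p - r[2:4])^2) < r[8]^2) -1 else 1
  } else if (organ$shape == "capsule") {
    a <- r[2:4]; b <- r[5:7]
    ab <- b - a
    t <- min(1, max(0, sum((p - a) * ab) / sum(ab^2)))
    if (sum((p - a - t * ab)^2) < r[8]^2) -1 else 1
  } else {
    if (all(abs(p - r[2:4]) < r[5:7])) -1 else 1
  }
}

oracle_organ_distance <- function(p, organ, n = 60000) {
  surf <- sample_organ_surface(organ, n)
  d <- min(sqrt(colSums((t(surf) - p)^2)))
  d * oracle_sdf_sign(p, organ)
}

sample_organ_surface <- function(organ, n) {
  r <- organ$row
  if (organ$shape == "sphere") {
    u <- fib_sphere(n)
    sweep(u * r[8], 2, r[2:4], "+")
  } else if (organ$shape == "capsule") {
    a <- r[2:4]; b <- r[5:7]; rad <- r[8]
    axis <- b - a; len <- sqrt(sum(axis^2))
    n_cyl <- round(n / 2)
    u <- axis / len
    perp1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- perp1 - sum(perp1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    circ <- 2 * pi * rad
    n_t <- max(2L, ceiling(sqrt(n_cyl * len / circ)))
    n_th <- max(8L, ceiling(n_cyl / n_t))
    g <- expand.grid(t = seq(0, 1, length.out = n_t),
                     th = seq(0, 2 * pi, length.out = n_th))
    cyl <- t(sapply(seq_len(nrow(g)), function(i)
      a + g$t[i] * axis + rad * (cos(g$th[i]) * e1 + sin(g$th[i]) * e2)))
    caps <- rbind(sweep(fib_sphere(round(n / 4)) * rad, 2, a, "+"),
                  sweep(fib_sphere(round(n / 4)) * rad, 2, b, "+"))
    # keep only cap points on the outward hemispheres
    keep_a <- (caps[seq_len(round(n / 4)), ] %*% u) <= sum(a * u) + 1e-12
    keep_b <- (caps[-seq_len(round(n / 4)), ] %*% u) >= sum(b * u) - 1e-12
    rbind(cyl, caps[c(keep_a, keep_b), , drop = FALSE])
  } else {
    ctr <- r[2:4]; he <- r[5:7]
    k <- ceiling(sqrt(n / 6))
    g <- as.matrix(expand.grid(seq(-1, 1, length.out = k),
                               seq(-1, 1, length.out = k)))
    faces <- list(cbind(1, g), cbind(-1, g), cbind(g[, 1], 1, g[, 2]),
                  cbind(g[, 1], -1, g[, 2]), cbind(g, 1), cbind(g, -1))
    pts <- do.call(rbind, faces)
    sweep(sweep(pts, 2, he, "*"), 2, ctr, "+")
  }
}

fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(cos(th) * sin(phi), sin(th) * sin(phi), cos(phi))
}

# --- exhaustive simple-path enumeration ----------------------------------
oracle_all_paths <- function(edges, lengths, from, to) {
  adj <- list()
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    adj[[e$from]] <- rbind(adj[[e$from]], data.frame(to = e$to, w = lengths[k]))
    adj[[e$to]] <- rbind(adj[[e$to]], data.frame(to = e$from, w = lengths[k]))
  }
  paths <- list()
  walk <- function(node, visited, len) {
    if (node == to) {
      paths[[length(paths) + 1]] <<- list(path = visited, len = len)
      return()
    }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (i in seq_len(nrow(nb))) {
      if (!nb$to[i] %in% visited)
        walk(nb$to[i], c(visited, nb$to[i]), len + nb$w[i])
    }
  }
  walk(from, from, 0)
  paths
}

oracle_best_path <- function(edges, lengths, from, to) {
  paths <- oracle_all_paths(edges, lengths, from, to)
  if (length(paths) == 0) return(NULL)
  key <- function(p) list(p$len, length(p$path), paste(p$path, collapse = "\r"))
  best <- paths[[1]]
  for (p in paths[-1]) {
    tol <- 1e-9 * max(1, best$len)
    if (p$len < best$len - tol ||
        (abs(p$len - best$len) <= tol &&
         (length(p$path) < length(best$path) ||
          (length(p$path) == length(best$path) &&
           paste(p$path, collapse = "\r") < paste(best$path, collapse = "\r")))))
      best <- p
  }
  best$path
}

# --- excursion-counting replay state machine -----------------------------
# positions: per-step tip trace; counts inside->outside transitions of the
# containment signal, starting from a contained state.
oracle_count_excursions <- function(positions, fixture = NULL, organs = NULL) {
  inside <- TRUE
  count <- 0L
  for (i in seq_len(nrow(positions))) {
    p <- positions[i, 1:3]
    now_inside <- if (!is.null(fixture)) {
      distance_to_centerline(p, fixture)$distance <= fixture$radius
    } else {
      min(vapply(organs, function(o) organ_distance(p, o), numeric(1))) >= 0
    }
    if (inside && !now_inside) count <- count + 1L
    inside <- now_inside
  }
  count
}

# --- definitional mixed-design ANOVA (explicit loops over cells) ---------
oracle_rm_anova <- function(df) {
  subjects <- unique(df$subject)
  reps <- sort(unique(df$repetition))
  groups <- sort(unique(as.character(df$group)))
  val <- function(s, k) df$value[df$subject == s & df$repetition == k]
  gof <- function(s) as.character(df$group[df$subject == s][1])
  gm <- mean(df$value)
  n <- length(subjects) / length(groups)
  m <- length(reps)
  subj_mean <- sapply(subjects, function(s) mean(sapply(reps, function(k) val(s, k))))
  grp_mean <- sapply(groups, function(g) mean(df$value[df$group == g]))
  rep_mean <- sapply(reps, function(k) mean(df$value[df$repetition == k]))
  cell_mean <- outer(groups, reps, Vectorize(function(g, k)
    mean(df$value[df$group == g & df$repetition == k])))
  ss_group <- n * m * sum((grp_mean - gm)^2)
  ss_subj <- m * sum((subj_mean - grp_mean[match(sapply(subjects, gof), groups)])^2)
  ss_rep <- n * length(groups) * sum((rep_mean - gm)^2)
  ss_int <- 0
  for (i in seq_along(groups)) for (j in seq_along(reps))
    ss_int <- ss_int + n * (cell_mean[i, j] - grp_mean[i] - rep_mean[j] + gm)^2
  ss_err <- 0
  for (s in subjects) for (j in seq_along(reps)) {
    g <- match(gof(s), groups)
    ss_err <- ss_err + (val(s, reps[j]) - cell_mean[g, j] -
                        subj_mean[match(s, subjects)] + grp_mean[g])^2
  }
  list(ss_group = as.numeric(ss_group), ss_subj = as.numeric(ss_subj),
       ss_rep = as.numeric(ss_rep), ss_int = as.numeric(ss_int),
       ss_err = as.numeric(ss_err),
       df = c(group = length(groups) - 1,
              subj = length(groups) * (n - 1), rep = m - 1,
              int = (length(groups) - 1) * (m - 1),
              err = length(groups) * (n - 1) * (m - 1)))
}

# simple reshape used by stats tests (independent of the package internals)
long_to_wide_oracle <- function(tab) {
  subjects <- unique(tab$subject)
  reps <- sort(unique(tab$repetition))
  Y <- matrix(NA_real_, length(subjects), length(reps),
              dimnames = list(subjects, reps))
  for (i in seq_len(nrow(tab)))
    Y[match(tab$subject[i], subjects), match(tab$repetition[i], reps)] <- tab$value[i]
  groups <- factor(tab$group[match(subjects, tab$subject)])
  list(Y = Y, groups = groups)
}

events_df_of <- function(rec) {
  do.call(rbind, lapply(rec$events, function(e) c(e$t, e$position, e$penetration)))
}

# random balanced long table with subject random intercepts
random_long_table <- function(n_per_group = 4, m = 5, effect = 0, seed = 1) {
  set.seed(seed)
  subj <- c(sprintf("b%02d", 1:n_per_group), sprintf("e%02d", 1:n_per_group))
  grp <- rep(c("beginner", "expert"), each = n_per_group)
  intercept <- rnorm(length(subj), sd = 0.5)
  df <- expand.grid(subject = subj, repetition = 1:m, stringsAsFactors = FALSE)
  idx <- match(df$subject, subj)
  df$group <- grp[idx]
  df$value <- rnorm(nrow(df)) + ifelse(df$group == "beginner", effect, 0) +
    intercept[idx]
  long_table(df)
}
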