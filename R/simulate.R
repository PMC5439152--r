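# Synthetic data: a Hudson-style ancestral-recombination-graph coalescent
# under piecewise-linear demography, pedigree gene dropping with
# per-centimorgan crossovers, marker-panel construction and masking.

#' Demography profile for the coalescent simulator
#'
#' Effective population size is piecewise linear in time (generations ago):
#' by default 100 at present, 1256 at 1,000, 4,350 at 10,000 and 43,500 at
#' 100,000 generations ago (constant beyond), with per-site mutation rate
#' 2.5e-8 and per-site recombination rate 1e-8.  One year is taken as one
#' generation.  All values are scalable for desk-scale runs.
#'
#' @param length_bp sequence length in base pairs.
#' @param mutation_rate per-site per-generation mutation rate.
#' @param recombination_rate per-site per-generation recombination rate.
#' @param times breakpoints in generations ago (non-decreasing, first 0).
#' @param sizes effective sizes at the breakpoints (positive).
#' @return a `demography` list.
#' @export
sim_demography <- function(length_bp = 1e6, mutation_rate = 2.5e-8,
                           recombination_rate = 1e-8,
                           times = c(0, 1000, 10000, 100000),
                           sizes = c(100, 1256, 4350, 43500)) {
  stopifnot(all(sizes > 0), !is.unsorted(times), times[1] == 0,
            length(times) == length(sizes))
  structure(list(length_bp = length_bp, mu = mutation_rate,
                 rr = recombination_rate, times = times, sizes = sizes),
            class = "demography")
}

ne_at <- function(demog, t) {
  k <- length(demog$times)
  if (t >= demog$times[k]) return(demog$sizes[k])
  i <- findInterval(t, demog$times)
  t0 <- demog$times[i]
  t1 <- demog$times[i + 1]
  demog$sizes[i] + (demog$sizes[i + 1] - demog$sizes[i]) * (t - t0) / (t1 - t0)
}

# integral of 1 / (2 Ne(u)) du from t0 to t1 (coalescent intensity)
coal_intensity <- function(demog, t0, t1) {
  if (t1 <= t0) return(0)
  ts <- demog$times
  total <- 0
  lo <- t0
  while (lo < t1) {
    i <- findInterval(lo, ts)
    hi <- if (i >= length(ts)) t1 else min(t1, ts[i + 1])
    n0 <- ne_at(demog, lo)
    n1 <- ne_at(demog, hi)
    if (abs(n1 - n0) < 1e-12) {
      total <- total + (hi - lo) / (2 * n0)
    } else {
      b <- (n1 - n0) / (hi - lo)
      total <- total + log(n1 / n0) / (2 * b)
    }
    lo <- hi
  }
  total
}

# ---- interval-set helpers (matrices with columns left, right, node) --------

seg_len <- function(segs) if (nrow(segs) == 0) 0 else sum(segs[, 2] - segs[, 1])

# flatten a list of interval sets to a union (2-col matrix)
seg_union_all <- function(seg_list) {
  mats <- seg_list[vapply(seg_list, nrow, 1L) > 0]
  if (!length(mats)) return(matrix(numeric(0), ncol = 2))
  allm <- do.call(rbind, lapply(mats, function(m) m[, 1:2, drop = FALSE]))
  allm <- allm[order(allm[, 1]), , drop = FALSE]
  out <- matrix(numeric(0), ncol = 2)
  cl <- allm[1, 1]; cr <- allm[1, 2]
  if (nrow(allm) > 1) {
    for (r in 2:nrow(allm)) {
      if (allm[r, 1] <= cr) {
        cr <- max(cr, allm[r, 2])
      } else {
        out <- rbind(out, c(cl, cr))
        cl <- allm[r, 1]; cr <- allm[r, 2]
      }
    }
  }
  rbind(out, c(cl, cr))
}

#' Simulate base haplotypes under the coalescent with recombination
#'
#' A discrete-sample, continuous-time ancestral-recombination-graph
#' simulation: pairwise coalescence at rate `1 / (2 Ne(t))` under the
#' piecewise-linear demography, lineage recombination at the per-site rate
#' times the lineage's ancestral-material length, marginal trees pruned as
#' soon as a region finds its MRCA.  Mutations are dropped on the graph at
#' the per-site rate and emitted as biallelic segregating sites.
#'
#' @param demog a [sim_demography()] profile.
#' @param n_haplotypes number of sampled haplotypes (>= 2).
#' @return list with `haplotypes` (n x S 0/1 matrix), `positions_bp`
#'   (sorted, unique) and `positions_cM`.
#' @export
simulate_base_haplotypes <- function(demog, n_haplotypes) {
  stopifnot(n_haplotypes >= 2)
  n <- as.integer(n_haplotypes)
  L <- demog$length_bp
  # lineages: per lineage a (left, right, node) matrix
  lin <- lapply(seq_len(n), function(i) matrix(c(0, L, i), ncol = 3))
  node_time <- rep(0, n)
  ecap <- 4L * n
  e_par <- integer(ecap); e_chl <- integer(ecap)
  e_l <- numeric(ecap); e_r <- numeric(ecap)
  ne <- 0L
  push_edges <- function(parent, segs) {
    m <- nrow(segs)
    if (ne + m > ecap) {
      newcap <- max(2L * ecap, ne + m)
      length(e_par) <<- newcap; length(e_chl) <<- newcap
      length(e_l) <<- newcap; length(e_r) <<- newcap
      ecap <<- newcap
    }
    idx <- ne + seq_len(m)
    e_par[idx] <<- parent
    e_chl[idx] <<- as.integer(segs[, 3])
    e_l[idx] <<- segs[, 1]
    e_r[idx] <<- segs[, 2]
    ne <<- ne + m
  }
  t <- 0
  while (length(lin) > 1) {
    k <- length(lin)
    mat_len <- vapply(lin, seg_len, numeric(1))
    lam_r <- demog$rr * sum(mat_len)
    cpairs <- k * (k - 1) / 2
    # next event time: solve lam_r * dt + cpairs * Lambda(t, t + dt) = E
    E <- stats::rexp(1)
    f <- function(dt) lam_r * dt + cpairs * coal_intensity(demog, t, t + dt) - E
    hi <- 1
    while (f(hi) < 0) hi <- hi * 2
    dt <- stats::uniroot(f, c(0, hi), tol = 1e-8 * max(hi, 1))$root
    t <- t + dt
    lam_c <- cpairs / (2 * ne_at(demog, t))
    if (runif(1) < lam_c / (lam_c + lam_r)) {
      # coalescence
      pair <- sample.int(k, 2)
      a <- lin[[pair[1]]]
      b <- lin[[pair[2]]]
      u <- length(node_time) + 1L
      node_time <- c(node_time, t)
      if (nrow(a)) push_edges(u, a)
      if (nrow(b)) push_edges(u, b)
      merged <- rbind(a, b)
      if (nrow(merged)) {
        merged[, 3] <- u
        merged <- seg_union_to_segs(merged, u)
      }
      lin <- lin[-pair]
      # prune material whose MRCA is now found (no other lineage carries it)
      if (nrow(merged)) {
        others <- seg_union_all(lin)
        if (nrow(others) == 0) {
          merged <- merged[0, , drop = FALSE]
        } else {
          # keep only the parts overlapping material still held elsewhere
          merged <- seg_intersect_keep(merged, others)
        }
      }
      if (nrow(merged)) lin[[length(lin) + 1L]] <- merged
    } else {
      # recombination: choose lineage by material length, breakpoint within
      li <- sample.int(k, 1, prob = mat_len)
      segs <- lin[[li]]
      lens <- segs[, 2] - segs[, 1]
      si <- sample.int(nrow(segs), 1, prob = lens)
      x <- runif(1, segs[si, 1], segs[si, 2])
      leftm <- segs[segs[, 2] <= x, , drop = FALSE]
      rightm <- segs[segs[, 1] >= x, , drop = FALSE]
      mid <- segs[segs[, 1] < x & segs[, 2] > x, , drop = FALSE]
      if (nrow(mid)) {
        leftm <- rbind(leftm, c(mid[1, 1], x, mid[1, 3]))
        rightm <- rbind(c(x, mid[1, 2], mid[1, 3]), rightm)
      }
      if (nrow(leftm) && nrow(rightm)) {
        lin[[li]] <- leftm
        lin[[length(lin) + 1L]] <- rightm
      } # else the breakpoint fell outside material; nothing changes
    }
    lin <- lin[vapply(lin, nrow, 1L) > 0]
    if (!length(lin)) break
  }
  # mutations on edges
  if (ne == 0L) {
    return(list(haplotypes = matrix(0L, n, 0), positions_bp = numeric(0),
                positions_cM = numeric(0)))
  }
  e_par <- e_par[seq_len(ne)]; e_chl <- e_chl[seq_len(ne)]
  e_l <- e_l[seq_len(ne)]; e_r <- e_r[seq_len(ne)]
  dtv <- node_time[e_par] - node_time[e_chl]
  nmut <- rpois(ne, demog$mu * (e_r - e_l) * dtv)
  tot <- sum(nmut)
  if (tot == 0) {
    return(list(haplotypes = matrix(0L, n, 0), positions_bp = numeric(0),
                positions_cM = numeric(0)))
  }
  medge <- rep.int(seq_len(ne), nmut)
  mpos <- runif(tot, e_l[medge], e_r[medge])
  ord <- order(mpos)
  mpos <- mpos[ord]
  medge <- medge[ord]
  # group mutations by elementary tree interval and collect descendants
  brk <- sort(unique(c(e_l, e_r)))
  grp <- findInterval(mpos, brk)
  H <- matrix(0L, nrow = n, ncol = tot)
  for (g in unique(grp)) {
    xs <- which(grp == g)
    lo <- brk[g]
    active <- which(e_l <= lo & e_r > lo)
    kids <- split(e_chl[active], e_par[active])
    for (j in xs) {
      start <- e_chl[medge[j]]
      stack <- start
      repeat {
        leaves <- stack[stack <= n]
        if (length(leaves)) H[leaves, j] <- 1L
        inner <- as.character(stack[stack > n])
        if (!length(inner)) break
        stack <- unlist(kids[inner], use.names = FALSE)
        if (is.null(stack) || !length(stack)) break
      }
    }
  }
  keep <- !duplicated(mpos)
  H <- H[, keep, drop = FALSE]
  mpos <- mpos[keep]
  list(haplotypes = H, positions_bp = mpos,
       positions_cM = mpos * demog$rr * 100)
}

# merge touching intervals of one lineage after relabelling to a single node
seg_union_to_segs <- function(segs, node) {
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  out <- matrix(numeric(0), ncol = 3)
  cl <- segs[1, 1]; cr <- segs[1, 2]
  if (nrow(segs) > 1) {
    for (r in 2:nrow(segs)) {
      if (segs[r, 1] <= cr + 1e-12) {
        cr <- max(cr, segs[r, 2])
      } else {
        out <- rbind(out, c(cl, cr, node))
        cl <- segs[r, 1]; cr <- segs[r, 2]
      }
    }
  }
  rbind(out, c(cl, cr, node))
}

# intersect a labelled segment set with a plain union (2-col matrix)
seg_intersect_keep <- function(segs, keep) {
  out <- matrix(numeric(0), ncol = 3)
  for (r in seq_len(nrow(segs))) {
    l <- segs[r, 1]; rr <- segs[r, 2]; nd <- segs[r, 3]
    ov <- keep[keep[, 2] > l & keep[, 1] < rr, , drop = FALSE]
    for (s in seq_len(nrow(ov))) {
      out <- rbind(out, c(max(l, ov[s, 1]), min(rr, ov[s, 2]), nd))
    }
  }
  out
}

#' Pedigree design for gene dropping
#'
#' Defaults follow a 25-sire x 500-dam design producing 1000 progeny per
#' generation for 5 generations; all counts are scalable.
#'
#' @param n_sires,n_dams,n_progeny,n_generations positive integers;
#'   `n_dams >= n_sires` and `n_progeny >= 2 * n_dams` when more than one
#'   generation is bred from the progeny.
#' @return a `sim_pedigree_spec` list.
#' @export
sim_pedigree_spec <- function(n_sires = 25, n_dams = 500, n_progeny = 1000,
                              n_generations = 5) {
  stopifnot(n_sires > 0, n_dams >= n_sires, n_progeny > 0, n_generations > 0)
  structure(list(n_sires = n_sires, n_dams = n_dams, n_progeny = n_progeny,
                 n_generations = n_generations), class = "sim_pedigree_spec")
}

#' Found a pedigree from base haplotypes and gene-drop genotypes
#'
#' Founders draw two base haplotypes each (distinct within an individual);
#' later generations inherit recombined parental gametes.  Crossovers occur
#' with 1% probability per cM, uniformly placed, without interference.
#'
#' @param pool base haplotype matrix from [simulate_base_haplotypes()].
#' @param spec a [sim_pedigree_spec()].
#' @param positions_cM marker positions in cM.
#' @return list with `ped` (a [pedigree()] with a `generation` column) and
#'   `phase` (2n x S truth matrix; rows 2i-1 / 2i are paternal / maternal).
#' @export
found_and_drop <- function(pool, spec, positions_cM) {
  S <- ncol(pool)
  total_cM <- if (S) max(positions_cM) - min(positions_cM) else 0
  pos0 <- positions_cM - if (S) min(positions_cM) else 0
  nf <- spec$n_sires + spec$n_dams
  ntot <- nf + spec$n_generations * spec$n_progeny
  ids <- character(ntot)
  sires <- rep(NA_character_, ntot)
  dams <- rep(NA_character_, ntot)
  sex <- character(ntot)
  gen <- integer(ntot)
  ids[seq_len(nf)] <- paste0("F", seq_len(nf))
  sex[seq_len(nf)] <- c(rep("M", spec$n_sires), rep("F", spec$n_dams))
  P <- matrix(0L, nrow = 2L * ntot, ncol = S)
  for (i in seq_len(nf)) {
    hp <- sample.int(nrow(pool), 2)
    P[2L * i - 1L, ] <- pool[hp[1], ]
    P[2L * i, ] <- pool[hp[2], ]
  }
  meiosis <- function(g1, g2) {
    nint <- max(1L, ceiling(total_cM))
    ncross <- rbinom(1, nint, 0.01 * total_cM / nint)
    if (ncross == 0L || S == 0L) {
      return(if (runif(1) < 0.5) g1 else g2)
    }
    cuts <- sort(runif(ncross, 0, total_cM))
    segi <- findInterval(pos0, cuts)
    pick <- (segi + (runif(1) < 0.5)) %% 2L == 0L
    out <- g2
    out[pick] <- g1[pick]
    out
  }
  nxt <- nf
  for (g in seq_len(spec$n_generations)) {
    prev <- which(gen[seq_len(nxt)] == g - 1L)
    sire_pool <- prev[sex[prev] == "M"]
    dam_pool <- prev[sex[prev] == "F"]
    if (g > 1L) {
      sire_pool <- sample(sire_pool, min(spec$n_sires, length(sire_pool)))
      dam_pool <- sample(dam_pool, min(spec$n_dams, length(dam_pool)))
    }
    for (j in seq_len(spec$n_progeny)) {
      i <- nxt + 1L
      s <- sample(sire_pool, 1)
      d <- sample(dam_pool, 1)
      ids[i] <- paste0("G", g, "_", j)
      sires[i] <- ids[s]
      dams[i] <- ids[d]
      sex[i] <- if (j %% 2L) "M" else "F"
      gen[i] <- g
      P[2L * i - 1L, ] <- meiosis(P[2L * s - 1L, ], P[2L * s, ])
      P[2L * i, ] <- meiosis(P[2L * d - 1L, ], P[2L * d, ])
      nxt <- i
    }
  }
  ped <- pedigree(ids, ifelse(is.na(sires), "0", sires),
                  ifelse(is.na(dams), "0", dams))
  perm <- match(ped$id, ids)
  ped$generation <- gen[perm]
  ped$sex <- sex[perm]
  # align gamete rows with the (topologically sorted) pedigree order
  rows <- as.vector(rbind(2L * perm - 1L, 2L * perm))
  list(ped = ped, phase = P[rows, , drop = FALSE])
}

#' Construct high- and low-density marker panels
#'
#' The high-density panel is a uniform random subset of the segregating
#' sites; every low-density panel is a uniform random subset of the
#' high-density panel.
#'
#' @param n_sites number of segregating sites available.
#' @param hd_size high-density panel size.
#' @param ld_sizes named integer vector of low-density panel sizes.
#' @return list with sorted index vectors `hd` (into the sites) and `ld`
#'   (each into the columns of the high-density panel).
#' @export
make_panels <- function(n_sites, hd_size, ld_sizes) {
  if (n_sites < hd_size) {
    stop("only ", n_sites, " segregating sites; cannot build an HD panel of ",
         hd_size)
  }
  stopifnot(all(ld_sizes <= hd_size))
  hd <- sort(sample.int(n_sites, hd_size))
  ld <- lapply(ld_sizes, function(sz) sort(sample.int(hd_size, sz)))
  list(hd = hd, ld = ld)
}

#' Mask genotypes of test individuals to a low-density panel
#'
#' Test individuals keep the low-density markers only (all other high-density
#' markers set to 9); training individuals keep the full high-density panel.
#'
#' @param genotypes n x M truth genotype matrix over the HD panel.
#' @param ld_idx columns of the HD panel retained at low density.
#' @param test_rows row indices of the test individuals.
#' @return masked copy of `genotypes`.
#' @export
mask_genotypes <- function(genotypes, ld_idx, test_rows) {
  out <- genotypes
  if (length(test_rows)) {
    drop_cols <- setdiff(seq_len(ncol(genotypes)), ld_idx)
    out[test_rows, drop_cols] <- MISSING
  }
  out
}

#' Remove pedigree links of selected individuals
#'
#' The selected individuals get unknown sire and dam (treated as unrelated);
#' everything else, including their genotypes, is unchanged.
#'
#' @param ped a [pedigree()].
#' @param ids ids whose parent links are removed.
#' @return modified pedigree (same row order).
#' @export
drop_pedigree_links <- function(ped, ids) {
  rows <- match(ids, ped$id)
  stopifnot(!anyNA(rows))
  ped$sire[rows] <- NA_character_
  ped$dam[rows] <- NA_character_
  ped$sire_idx <- match(ped$sire, ped$id)
  ped$dam_idx <- match(ped$dam, ped$id)
  ped
}

#' Simulate a complete study population
#'
#' Runs the coalescent, founds a pedigree, gene-drops gametes, builds the
#' marker panels and masks the last generation to each low-density panel.
#'
#' @param seed integer seed governing all randomness.
#' @param demog a [sim_demography()].
#' @param spec a [sim_pedigree_spec()].
#' @param n_base_haplotypes base haplotype count (default 1000).
#' @param hd_size high-density panel size.
#' @param ld_sizes named vector of low-density panel sizes.
#' @param n_remove_links number of last-generation individuals whose pedigree
#'   links are removed (0 keeps the full pedigree).
#' @return a `sim_population` list: `ped`, `truth_phase` (2n x M over the HD
#'   panel), `truth_geno`, `masked` (named list of masked genotype matrices,
#'   one per LD panel), `panels`, `map_cM`, `test_ids`, `removed_ids`.
#' @export
simulate_population <- function(seed, demog = sim_demography(),
                                spec = sim_pedigree_spec(),
                                n_base_haplotypes = 1000,
                                hd_size = 2000,
                                ld_sizes = c(L15 = 15, L30 = 30, L300 = 300,
                                             L600 = 600, L2k = 2000),
                                n_remove_links = 0) {
  set.seed(child_seed(seed, 101L))
  pool <- simulate_base_haplotypes(demog, n_base_haplotypes)
  set.seed(child_seed(seed, 102L))
  dropped <- found_and_drop(pool$haplotypes, spec, pool$positions_cM)
  set.seed(child_seed(seed, 103L))
  ld_sizes <- pmin(ld_sizes, hd_size)
  panels <- make_panels(ncol(pool$haplotypes), hd_size, ld_sizes)
  ped <- dropped$ped
  n <- nrow(ped)
  Pfull <- dropped$phase[, panels$hd, drop = FALSE]
  G <- Pfull[pat_rows(n), , drop = FALSE] + Pfull[mat_rows(n), , drop = FALSE]
  storage.mode(G) <- "integer"
  rownames(G) <- ped$id
  test_ids <- ped$id[ped$generation == max(ped$generation)]
  test_rows <- match(test_ids, ped$id)
  masked <- lapply(panels$ld, function(idx) mask_genotypes(G, idx, test_rows))
  removed_ids <- character(0)
  if (n_remove_links > 0) {
    set.seed(child_seed(seed, 104L))
    removed_ids <- sample(test_ids, min(n_remove_links, length(test_ids)))
  }
  structure(list(ped = ped, truth_phase = Pfull, truth_geno = G,
                 masked = masked, panels = panels,
                 map_cM = pool$positions_cM[panels$hd],
                 test_ids = test_ids, removed_ids = removed_ids),
            class = "sim_population")
}
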