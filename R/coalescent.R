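# Coalescent engine ----------------------------------------------------------
#
# Neutral genealogies under constant-size, island-structured, exponentially
# growing, and metapopulation (extinction/recolonization) demographies, with
# infinite-sites mutation.  Time is measured in units of 2N generations and
# theta = 4N*mu, so classical expectations apply directly:
# E[T_MRCA(2)] = 1, E[S] = theta * sum_{i<n} 1/i.

#' Specify a demography for the coalescent engine
#'
#' @param n_demes Number of demes (1 = panmixia).
#' @param deme_sizes Relative deme sizes (length `n_demes`).
#' @param migration_rate Scaled migration rate 4Nm: total emigration rate per
#'   lineage is `migration_rate/2`, split evenly among the other demes
#'   (island model) unless `mig_weights` is given.
#' @param growth_rate Scaled exponential growth rate alpha; backwards in time
#'   the coalescence hazard grows as `exp(alpha * t)`. 0 = constant size.
#' @param selfing_rate Selfing probability s in `[0,1]`, consumed by
#'   [diploidize()]; at equilibrium the autozygosity is `F = s/(2-s)`.
#' @param mig_weights Optional `n_demes x n_demes` matrix of relative
#'   between-deme migration weights (diagonal ignored), e.g. a stepping-stone
#'   adjacency; rows are the deme a lineage leaves (backwards in time).
#' @param extinction_rate Scaled per-deme extinction/recolonization rate; on
#'   an event all lineages of the deme jump to one random source deme
#'   (propagule recolonization viewed backwards in time).
#' @param pool_time Time (units of 2N) at which all demes merge into one
#'   ancestral panmictic pool; `Inf` disables pooling.  Used to give patchily
#'   structured scenarios a finite common ancestor even without migration.
#' @param ne_scale_inbreeding If `TRUE`, rescale coalescent time by
#'   `1/(1+F)` to mimic the within-genealogy effective-size reduction caused
#'   by partial selfing; off by default (selfing is otherwise modeled only at
#'   the diploidization step).
#' @return A `demography_model` object.
#' @export
demography_model <- function(n_demes = 1L, deme_sizes = rep(1, n_demes),
                             migration_rate = 0, growth_rate = 0,
                             selfing_rate = 0, mig_weights = NULL,
                             extinction_rate = 0, pool_time = Inf,
                             ne_scale_inbreeding = FALSE) {
  n_demes <- as.integer(n_demes)
  stopifnot(n_demes >= 1L, length(deme_sizes) == n_demes, all(deme_sizes > 0),
            migration_rate >= 0, extinction_rate >= 0, pool_time > 0)
  if (selfing_rate < 0 || selfing_rate > 1) stop("selfing_rate must be in [0,1]")
  if (!is.null(mig_weights)) {
    mig_weights <- as.matrix(mig_weights)
    stopifnot(nrow(mig_weights) == n_demes, ncol(mig_weights) == n_demes,
              all(mig_weights >= 0))
    diag(mig_weights) <- 0
  }
  structure(list(n_demes = n_demes, deme_sizes = as.numeric(deme_sizes),
                 migration_rate = migration_rate, growth_rate = growth_rate,
                 selfing_rate = selfing_rate, mig_weights = mig_weights,
                 extinction_rate = extinction_rate, pool_time = pool_time,
                 ne_scale_inbreeding = ne_scale_inbreeding),
            class = "demography_model")
}

#' Simulate a coalescent genealogy
#'
#' Structured coalescent with exponential waiting times: within deme `d` with
#' `k_d` lineages the coalescence hazard is `choose(k_d,2)/size_d` (times
#' `exp(alpha*t)` under growth), each lineage emigrates at rate
#' `migration_rate/2`, and each occupied deme suffers extinction at rate
#' `extinction_rate`.
#'
#' @param n Number of sampled haploid lineages (>= 2).
#' @param model A [demography_model()].
#' @param seed Optional RNG seed (reproducibility contract: same seed, same
#'   tree).
#' @param leaf_deme Optional integer vector assigning each leaf to a deme;
#'   defaults to round-robin over demes.
#' @return A `coal_tree`: nodes `1..n` are leaves, `2n-1` is the root;
#'   fields `parent`, `blen` (branch to parent), `node_time`, `leaf_deme`,
#'   `tmrca`.
#' @export
simulate_tree <- function(n, model = demography_model(), seed = NULL,
                          leaf_deme = NULL) {
  if (n < 2L) stop("need n >= 2 lineages")
  if (!is.null(seed)) set.seed(seed)
  nd <- model$n_demes
  if (is.null(leaf_deme))
    leaf_deme <- if (nd == 1L) rep(1L, n) else rep(seq_len(nd), length.out = n)
  leaf_deme <- as.integer(leaf_deme)
  if (any(leaf_deme < 1L | leaf_deme > nd)) stop("leaf deme out of range")
  if (nd > 1L && model$migration_rate == 0 && model$extinction_rate == 0 &&
      !is.finite(model$pool_time) && length(unique(leaf_deme)) > 1L)
    stop("disconnected demes: no migration, extinction or pooling; ",
         "lineages sampled across demes never find a common ancestor")

  time_scale <- if (model$ne_scale_inbreeding) {
    Fq <- model$selfing_rate / (2 - model$selfing_rate)
    1 / (1 + Fq)
  } else 1
  alpha <- model$growth_rate
  nn <- 2L * n - 1L
  parent <- integer(nn); blen <- numeric(nn); ntime <- numeric(nn)
  act <- seq_len(n); act_deme <- leaf_deme
  t <- 0; nxt <- n + 1L
  pooled <- nd == 1L
  m2 <- model$migration_rate / 2

  repeat {
    k <- length(act)
    if (k == 1L) break
    k_d <- tabulate(act_deme, nd)
    sizes <- model$deme_sizes * time_scale
    crate <- sum(k_d * (k_d - 1) / 2 / sizes)
    mrate <- if (pooled) 0 else k * m2
    erate <- if (pooled) 0 else model$extinction_rate * sum(k_d > 0L)

    # candidate waiting times (competing risks; growth needs inversion)
    w_c <- if (crate > 0) {
      E <- stats::rexp(1)
      if (alpha == 0) E / crate
      else log(exp(alpha * t) + alpha * E / crate) / alpha - t
    } else Inf
    w_m <- if (mrate > 0) stats::rexp(1, mrate) else Inf
    w_e <- if (erate > 0) stats::rexp(1, erate) else Inf
    w <- min(w_c, w_m, w_e)

    if (!pooled && is.finite(model$pool_time) && t + w >= model$pool_time) {
      t <- model$pool_time
      act_deme[] <- 1L
      pooled <- TRUE
      next
    }
    if (!is.finite(w)) stop("no possible event; configuration disconnected")
    t <- t + w

    if (w == w_c) {
      pr <- k_d * (k_d - 1) / 2 / sizes
      d <- sample.int(nd, 1L, prob = pr)
      in_d <- which(act_deme == d)
      pick <- in_d[sample.int(length(in_d), 2L)]
      c1 <- act[pick[1L]]; c2 <- act[pick[2L]]
      parent[c1] <- nxt; parent[c2] <- nxt
      blen[c1] <- t - ntime[c1]; blen[c2] <- t - ntime[c2]
      ntime[nxt] <- t
      act <- c(act[-pick], nxt)
      act_deme <- c(act_deme[-pick], d)
      nxt <- nxt + 1L
    } else if (w == w_m) {
      li <- sample.int(k, 1L)
      from <- act_deme[li]
      wts <- if (is.null(model$mig_weights)) {
        v <- rep(1, nd); v[from] <- 0; v
      } else model$mig_weights[from, ]
      if (sum(wts) > 0)
        act_deme[li] <- sample.int(nd, 1L, prob = wts)
    } else {
      occ <- which(k_d > 0L)
      d <- if (length(occ) == 1L) occ else occ[sample.int(length(occ), 1L)]
      if (nd > 1L) {
        src <- sample.int(nd - 1L, 1L)
        src <- if (src >= d) src + 1L else src
        act_deme[act_deme == d] <- src
      }
    }
  }
  structure(list(n_leaves = n, parent = parent, blen = blen,
                 node_time = ntime, leaf_deme = leaf_deme,
                 tmrca = ntime[nn]),
            class = "coal_tree")
}

#' Total branch length of a genealogy
#' @param tree A `coal_tree`.
#' @export
total_tree_length <- function(tree) sum(tree$blen)

#' External (leaf) branch length of a genealogy
#' @param tree A `coal_tree`.
#' @export
external_tree_length <- function(tree) sum(tree$blen[seq_len(tree$n_leaves)])

# leaves below each node, as a list of integer vectors
.descendant_leaves <- function(tree) {
  nn <- 2L * tree$n_leaves - 1L
  desc <- vector("list", nn)
  for (i in seq_len(tree$n_leaves)) desc[[i]] <- i
  ord <- order(tree$node_time[(tree$n_leaves + 1L):nn])
  for (v in (tree$n_leaves + 1L):nn) desc[[v]] <- integer(0)
  for (child in order(tree$node_time[seq_len(nn)])) {
    p <- tree$parent[child]
    if (p > 0L) desc[[p]] <- c(desc[[p]], desc[[child]])
  }
  desc
}

.place_mutations <- function(tree, n_mut) {
  n <- tree$n_leaves
  if (n_mut == 0L)
    return(matrix(0L, nrow = n, ncol = 0L))
  nn <- 2L * n - 1L
  br <- tree$blen[-nn]  # root has no parent branch
  hit <- sample.int(nn - 1L, n_mut, replace = TRUE, prob = br)
  desc <- .descendant_leaves(tree)
  haps <- matrix(0L, nrow = n, ncol = n_mut)
  for (j in seq_len(n_mut)) haps[desc[[hit[j]]], j] <- 1L
  haps
}

#' Drop infinite-sites mutations on a genealogy at rate theta
#'
#' The mutation count is Poisson with mean `theta * L_total / 2` (branch
#' lengths in units of 2N, theta = 4N*mu) and each mutation lands on a branch
#' with probability proportional to its length, creating a new segregating
#' column (infinite sites).
#'
#' @param tree A `coal_tree`.
#' @param theta Scaled mutation rate 4N*mu (> 0).
#' @param seed Optional RNG seed.
#' @return A `sim_locus`: binary `haplotypes` matrix (leaves x segregating
#'   sites, 1 = derived), sorted uniform `positions`, and the `tree`.
#' @export
drop_mutations <- function(tree, theta, seed = NULL) {
  if (theta <= 0) stop("theta must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_mut <- stats::rpois(1L, theta * total_tree_length(tree) / 2)
  haps <- .place_mutations(tree, n_mut)
  structure(list(haplotypes = haps, positions = sort(stats::runif(n_mut)),
                 tree = tree),
            class = "sim_locus")
}

#' Drop exactly `s_obs` mutations on a genealogy (fixed-S conditioning)
#'
#' The DnaSP-style null: the number of segregating sites is fixed at the
#' observed value and each mutation is placed on a branch with probability
#' proportional to branch length.
#'
#' @param tree A `coal_tree`.
#' @param s_obs Non-negative number of mutations to place.
#' @param seed Optional RNG seed.
#' @return A `sim_locus` with exactly `s_obs` segregating columns.
#' @export
drop_fixed_s <- function(tree, s_obs, seed = NULL) {
  if (s_obs < 0) stop("s_obs must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  haps <- .place_mutations(tree, as.integer(s_obs))
  structure(list(haplotypes = haps,
                 positions = sort(stats::runif(as.integer(s_obs))),
                 tree = tree),
            class = "sim_locus")
}

#' Pair simulated haplotypes into diploids under partial selfing
#'
#' Haplotype rows `2i-1, 2i` form individual `i`.  With probability
#' `F = s/(2-s)` (the equilibrium autozygosity under selfing rate `s`) the
#' individual is autozygous and its first haplotype is duplicated; otherwise
#' it keeps two independent haplotypes.  Realized FIS converges to `F`.
#'
#' @param haps Matrix with an even number of rows (2 per individual).
#' @param selfing_rate Selfing probability s in `[0,1]`.
#' @param seed Optional RNG seed.
#' @return List with `haplotypes` (same shape, autozygous rows duplicated),
#'   `autozygous` (logical per individual) and `individual` (row -> diploid
#'   index map).
#' @export
diploidize <- function(haps, selfing_rate, seed = NULL) {
  if (selfing_rate < 0 || selfing_rate > 1)
    stop("selfing_rate must be in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  if (nrow(haps) %% 2L != 0L) stop("need an even number of haplotype rows")
  n_ind <- nrow(haps) %/% 2L
  Fq <- selfing_rate / (2 - selfing_rate)
  auto <- stats::runif(n_ind) < Fq
  for (i in which(auto)) haps[2L * i, ] <- haps[2L * i - 1L, ]
  list(haplotypes = haps, autozygous = auto,
       individual = rep(seq_len(n_ind), each = 2L))
}

#' Harmonic number a1 = sum_{i=1}^{n-1} 1/i
#' @param n Sample size.
#' @export
harmonic_a1 <- function(n) if (n < 2L) 0 else sum(1 / seq_len(n - 1L))
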