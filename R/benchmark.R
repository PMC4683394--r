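#' Parameters for the LFR-style benchmark generator
#'
#' Bundles and validates the parameters of [generate_lfr()]: networks with a
#' truncated power-law degree distribution (exponent `gamma` on
#' `[kmin, kmax]`), truncated power-law community sizes (exponent `beta` on
#' `[smin, smax]`) and a mixing parameter `mu`, the fraction of each node's
#' edges that leave its community.
#'
#' @param n Number of nodes.
#' @param kmin,kmax Degree bounds (inclusive).
#' @param gamma Degree power-law exponent (> 1).
#' @param beta Community-size power-law exponent (> 1, or exactly 1 for the
#'   flat-in-log limit used in the benchmark literature).
#' @param mu Mixing parameter in `[0, 1)`.
#' @param smin,smax Community-size bounds; `smin` must exceed `kmin` so every
#'   node fits in its community.
#' @param seed Optional RNG seed making the generated network reproducible.
#' @return A validated list of class `lfr_params`.
#' @export
lfr_params <- function(n = 5000, kmin = 15, kmax = 25, gamma = 2, beta = 1,
                       mu = 0.1, smin = 20, smax = 100, seed = NULL) {
  n <- as.integer(n)
  kmin <- as.integer(kmin)
  kmax <- as.integer(kmax)
  smin <- as.integer(smin)
  smax <- as.integer(smax)
  if (is.na(n) || n < 2L) rlang::abort("`n` must be an integer >= 2")
  if (kmin < 1L || kmin > kmax || kmax >= n) {
    rlang::abort("need 1 <= kmin <= kmax < n")
  }
  if (mu < 0 || mu >= 1) rlang::abort("`mu` must be in [0, 1)")
  if (gamma <= 1) rlang::abort("`gamma` must be > 1")
  if (beta < 1) rlang::abort("`beta` must be >= 1")
  if (smin <= kmin) rlang::abort("`smin` must exceed `kmin`")
  if (smin > smax || smax > n) rlang::abort("need smin <= smax <= n")
  structure(
    list(n = n, kmin = kmin, kmax = kmax, gamma = gamma, beta = beta,
         mu = mu, smin = smin, smax = smax, seed = seed),
    class = "lfr_params"
  )
}

#' @export
print.lfr_params <- function(x, ...) {
  cat(sprintf(
    "<lfr_params: n = %d, degree ~ k^-%g on [%d, %d], sizes ~ s^-%g on [%d, %d], mu = %g>\n",
    x$n, x$gamma, x$kmin, x$kmax, x$beta, x$smin, x$smax, x$mu
  ))
  invisible(x)
}

#' Sample a degree sequence from a truncated power law
#'
#' Draws `n` degrees with \eqn{P(k) \propto k^{-\gamma}} on
#' `[kmin, kmax]`; the sum is forced even (a requirement of stub matching) by
#' adjusting one degree within the bounds.
#'
#' @param p An `lfr_params` object (or arguments for [lfr_params()] via `...`).
#' @param ... Used to build `p` when it is not supplied.
#' @return Integer vector of `n` degrees.
#' @export
sample_degree_sequence <- function(p = NULL, ...) {
  p <- resolve_lfr_params(p, ...)
  with_optional_seed(p$seed, {
    ks <- p$kmin:p$kmax
    deg <- sample_int_powerlaw(ks, p$n, p$gamma)
    if (sum(deg) %% 2L == 1L) {
      up <- which(deg < p$kmax)
      if (length(up) > 0L) {
        deg[up[1L]] <- deg[up[1L]] + 1L
      } else {
        down <- which(deg > p$kmin)
        if (length(down) == 0L) {
          rlang::abort("cannot make degree sum even within [kmin, kmax]")
        }
        deg[down[1L]] <- deg[down[1L]] - 1L
      }
    }
    as.integer(deg)
  })
}

#' Sample community sizes from a truncated power law
#'
#' Draws sizes with \eqn{P(s) \propto s^{-\beta}} on `[smin, smax]` until they
#' sum to at least `total`, then adjusts the last size so the sum is exactly
#' `total`; draws whose adjustment would leave the bounds are rejected and
#' resampled (bounded retries).
#'
#' @inheritParams sample_degree_sequence
#' @param total Required sum of sizes (the node count).
#' @param retries Number of resampling attempts before giving up.
#' @return Integer vector of community sizes summing to `total`.
#' @export
sample_community_sizes <- function(p = NULL, total = NULL, retries = 1000, ...) {
  p <- resolve_lfr_params(p, ...)
  if (is.null(total)) total <- p$n
  if (total < p$smin) rlang::abort("`total` smaller than the minimum community size")
  with_optional_seed(p$seed, {
    ss <- p$smin:p$smax
    for (try in seq_len(retries)) {
      sizes <- integer()
      while (sum(sizes) < total) {
        sizes <- c(sizes, sample_int_powerlaw(ss, 1L, p$beta))
      }
      excess <- sum(sizes) - total
      last <- sizes[length(sizes)]
      if (excess == 0L) return(sizes)
      if (last - excess >= p$smin) {
        sizes[length(sizes)] <- last - excess
        return(as.integer(sizes))
      }
    }
    rlang::abort("could not partition `total` into sizes within [smin, smax]")
  })
}

#' Generate an LFR-style benchmark network with planted communities
#'
#' Simplified LFR construction: degrees and community sizes are drawn from
#' truncated power laws, each node splits its degree into
#' `round((1 - mu) * degree)` internal and the remaining external stubs (with
#' at least one internal stub when `mu < 1` and at least one external stub
#' when `mu > 0`), nodes are assigned to communities large enough to hold
#' their internal degree, and stubs are wired by configuration-model matching
#' with rejection of self-loops, duplicate edges and (for external stubs)
#' within-community edges. Unmatched residual stubs are dropped with a
#' message.
#'
#' @inheritParams sample_degree_sequence
#' @return A list with elements `graph` (a `ksim_graph`), `membership` (the
#'   planted partition tibble with columns `node`, `community`) and
#'   `dropped_stubs` (count of stubs that could not be matched).
#' @examples
#' net <- generate_lfr(lfr_params(n = 300, kmin = 5, kmax = 10, mu = 0.1,
#'                                smin = 12, smax = 50, seed = 1))
#' net$graph
#' @export
generate_lfr <- function(p = NULL, ...) {
  p <- resolve_lfr_params(p, ...)
  with_optional_seed(p$seed, {
    unseeded <- p
    unseeded$seed <- NULL
    deg <- sample_degree_sequence(unseeded)
    sizes <- sample_community_sizes(unseeded)

    # split degrees into internal / external stubs
    d_int <- as.integer(round((1 - p$mu) * deg))
    if (p$mu > 0) d_int <- pmin(d_int, deg - 1L)
    if (p$mu < 1) d_int <- pmax(d_int, 1L)
    # a node's internal degree cannot exceed its community size - 1
    d_int <- pmin(d_int, max(sizes) - 1L)

    # assign nodes to communities: largest internal degree first, into a
    # random community that still has room and is large enough
    q <- length(sizes)
    free <- sizes
    comm_of <- integer(p$n)
    for (v in order(d_int, decreasing = TRUE)) {
      ok <- which(free > 0L & sizes > d_int[v])
      if (length(ok) == 0L) {
        ok <- which(free > 0L) # fall back: cap the internal degree
        d_int[v] <- min(d_int[v], sizes[ok[1L]] - 1L)
      }
      pick <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = free[ok])
      comm_of[v] <- pick
      free[pick] <- free[pick] - 1L
      if (sizes[pick] - 1L < d_int[v]) d_int[v] <- sizes[pick] - 1L
    }
    d_ext <- deg - d_int

    edges_env <- new.env(hash = TRUE, size = sum(deg))
    edge_u <- integer(0)
    edge_v <- integer(0)
    dropped <- 0L

    add_edges <- function(a, b) {
      edge_u <<- c(edge_u, a)
      edge_v <<- c(edge_v, b)
      for (i in seq_along(a)) {
        assign(paste0(a[i], "_", b[i]), TRUE, envir = edges_env)
      }
    }
    is_edge <- function(a, b) {
      vapply(seq_along(a), function(i) {
        exists(paste0(a[i], "_", b[i]), envir = edges_env, inherits = FALSE)
      }, logical(1))
    }

    # match stubs by repeated random pairing with rejection
    match_stubs <- function(stubs, same_comm_forbidden, max_pass = 50L) {
      for (pass in seq_len(max_pass)) {
        nstub <- length(stubs)
        if (nstub < 2L) break
        s <- sample(stubs)
        if (nstub %% 2L == 1L) {
          stubs_left <- s[nstub]
          s <- s[-nstub]
        } else {
          stubs_left <- integer(0)
        }
        a <- pmin(s[c(TRUE, FALSE)], s[c(FALSE, TRUE)])
        b <- pmax(s[c(TRUE, FALSE)], s[c(FALSE, TRUE)])
        bad <- a == b | is_edge(a, b)
        if (same_comm_forbidden) bad <- bad | comm_of[a] == comm_of[b]
        # a batch can contain the same new pair twice
        key <- paste0(a, "_", b)
        bad <- bad | duplicated(key)
        if (any(!bad)) add_edges(a[!bad], b[!bad])
        stubs <- c(stubs_left, a[bad], b[bad])
        if (length(stubs) < 2L) break
        if (all(bad)) next
      }
      stubs
    }

    # internal wiring, one community at a time
    for (cc in seq_len(q)) {
      members <- which(comm_of == cc)
      stubs <- rep(members, d_int[members])
      left <- match_stubs(stubs, same_comm_forbidden = FALSE)
      dropped <- dropped + length(left)
    }
    # external wiring across the whole network
    stubs <- rep(seq_len(p$n), d_ext)
    left <- match_stubs(stubs, same_comm_forbidden = TRUE)
    dropped <- dropped + length(left)

    if (dropped > 0L) {
      message(sprintf("generate_lfr: dropped %d unmatched stub(s) of %d",
                      dropped, sum(deg)))
    }

    width <- nchar(as.character(p$n))
    labels <- sprintf(paste0("n%0", width, "d"), seq_len(p$n))
    g <- build_graph(
      data.frame(from = labels[edge_u], to = labels[edge_v]),
      nodes = labels
    )
    membership <- tibble::tibble(
      node = labels,
      community = sprintf("c%03d", comm_of)
    )[order_labels(labels), ]
    list(graph = g, membership = membership, dropped_stubs = dropped)
  })
}

#' Generate a planted-partition random graph
#'
#' `q` blocks of `s` nodes; each within-block pair is an edge with probability
#' `p_in`, each between-block pair with probability `p_out`. A controlled
#' fixture for unit tests: `p_in = 1, p_out = 0` gives `q` disjoint cliques.
#'
#' @param q Number of blocks (communities).
#' @param s Block size.
#' @param p_in,p_out Within/between-block edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed Optional RNG seed.
#' @return A list with elements `graph` and `membership` as in
#'   [generate_lfr()].
#' @export
generate_planted_partition <- function(q, s, p_in, p_out, seed = NULL) {
  q <- as.integer(q)
  s <- as.integer(s)
  if (is.na(q) || q < 1L || is.na(s) || s < 1L) {
    rlang::abort("`q` and `s` must be positive integers")
  }
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    rlang::abort("need 0 <= p_out < p_in <= 1")
  }
  n <- q * s
  with_optional_seed(seed, {
    block <- rep(seq_len(q), each = s)
    pairs <- utils::combn(n, 2L)
    a <- pairs[1L, ]
    b <- pairs[2L, ]
    prob <- ifelse(block[a] == block[b], p_in, p_out)
    keep <- stats::runif(length(prob)) < prob
    width <- nchar(as.character(n))
    labels <- sprintf(paste0("n%0", width, "d"), seq_len(n))
    g <- build_graph(
      data.frame(from = labels[a[keep]], to = labels[b[keep]]),
      nodes = labels
    )
    membership <- tibble::tibble(
      node = labels,
      community = sprintf("c%03d", block)
    )[order_labels(labels), ]
    list(graph = g, membership = membership)
  })
}

# ---- internal ---------------------------------------------------------------

# truncated power-law draw on the integer support `vals` (guards the
# base::sample scalar-support pitfall)
sample_int_powerlaw <- function(vals, n, expo) {
  if (length(vals) == 1L) return(rep(as.integer(vals), n))
  as.integer(sample(vals, n, replace = TRUE, prob = vals^(-expo)))
}

resolve_lfr_params <- function(p, ...) {
  if (is.null(p)) return(lfr_params(...))
  if (inherits(p, "lfr_params")) return(p)
  if (is.list(p)) return(do.call(lfr_params, p))
  rlang::abort("`p` must be an `lfr_params` object or a parameter list")
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
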