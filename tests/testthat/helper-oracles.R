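# Independent oracles and fixture builders used across test files.
# Each oracle re-derives the quantity from first principles, separately
# from the implementation path it checks.

# ---- tree fixtures -------------------------------------------------------

ladder_tree <- function(n, focal = "s1") {
  # caterpillar: focal nests deepest, s<n> attaches at the root
  nwk <- "s1"
  for (i in 2:n) nwk <- sprintf("(%s,s%d)", nwk, i)
  species_tree(paste0(nwk, ";"), focal)
}

balanced8_tree <- function() {
  species_tree("(((s1,s2),(s3,s4)),((s5,s6),(s7,s8)));", "s1")
}

droso_tree <- function() species_tree(default_drosophila_tree(), "D_melanogaster")

# ---- Dollo brute-force oracle --------------------------------------------

# Exhaustive minimal-gain-then-minimal-loss reconstruction. States are
# enumerated for every node; a gain is a 0->1 edge (or state 1 at the
# root, i.e. origination at or before the root); a loss is a 1->0 edge.
# Returns the optimal branch (attachment of the gain node to the
# root-to-focal path, youngest among ties) and the minimal loss count.
dollo_brute_force <- function(tree, calls) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  state_fixed <- rep(NA_integer_, nnode)
  idx <- match(names(calls), phy$tip.label)
  state_fixed[idx[calls == "present"]] <- 1L
  state_fixed[idx[calls == "absent"]] <- 0L

  free <- which(is.na(state_fixed))  # internal nodes + unknown tips
  k <- length(free)
  best <- NULL
  for (mask in 0:(2^k - 1)) {
    st <- state_fixed
    st[free] <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
    gains_edges <- which(st[phy$edge[, 1]] == 0L & st[phy$edge[, 2]] == 1L)
    gains <- length(gains_edges) + (st[root] == 1L)
    losses <- sum(st[phy$edge[, 1]] == 1L & st[phy$edge[, 2]] == 0L)
    gain_node <- if (st[root] == 1L) root else phy$edge[gains_edges, 2]
    cand <- list(gains = gains, losses = losses, gain_node = gain_node)
    if (is.null(best) || gains < best$gains ||
        (gains == best$gains && losses < best$losses)) {
      best <- cand
      best$gain_nodes <- gain_node
    } else if (gains == best$gains && losses == best$losses) {
      best$gain_nodes <- c(best$gain_nodes, gain_node)
    }
  }
  attach_idx <- function(node) {
    while (is.na(tree$path_index[node])) node <- tree$parent[node]
    tree$path_index[node]
  }
  branches <- vapply(unique(best$gain_nodes), attach_idx, integer(1))
  list(gains = best$gains, losses = best$losses,
       branch = max(branches), branches = sort(unique(branches)))
}

norm_calls <- function(x) {
  # numeric/NA vector -> character calls
  out <- ifelse(is.na(x), "unknown", ifelse(x == 1, "present", "absent"))
  names(out) <- names(x)
  out
}

# ---- Welch t oracle -------------------------------------------------------

welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# ---- Fisher enumeration oracle -------------------------------------------

# direct evaluation via binomial coefficients, independent of dhyper
fisher_oracle_two_sided <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); N <- sum(m)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(N, c1)
  p_obs <- probs[ks == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- qPCR well builder ----------------------------------------------------

wells_from_dct <- function(dct_kd, dct_ctrl, ref_ct = 15) {
  data.frame(
    gene_role = rep(c("target", "reference"), times = c(length(dct_kd) + length(dct_ctrl),
                                                        length(dct_kd) + length(dct_ctrl))),
    condition = rep(rep(c("knockdown", "control"),
                        times = c(length(dct_kd), length(dct_ctrl))), 2),
    replicate = rep(c(seq_along(dct_kd), seq_along(dct_ctrl)), 2),
    ct = c(ref_ct + dct_kd, ref_ct + dct_ctrl,
           rep(ref_ct, length(dct_kd) + length(dct_ctrl)))
  )
}
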