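#' Call a lethality phenotype from F1 progeny counts
#'
#' RNAi crosses segregate GFP-marked balancer (control) progeny from
#' non-GFP (knockdown) progeny; survival of the knockdown class relative to
#' the control class determines the call. With `r = nongfp / gfp`:
#' `lethal` if `r < lethal_cut`, `semi-lethal` if `lethal_cut <= r <
#' semi_cut`, otherwise `non-lethal`. A line with no control progeny
#' (`gfp == 0`) cannot be scored and is flagged `invalid`. Downstream
#' tables merge `semi-lethal` into `lethal` (see [merge_semi_lethal()]).
#'
#' @param gfp_count,nongfp_count Non-negative integer vectors (recycled).
#' @param lethal_cut,semi_cut Ratio thresholds; defaults 0.1 and 0.5. These
#'   are configurable conventions, not measured quantities.
#' @return Character vector in `lethal`/`semi-lethal`/`non-lethal`/`invalid`.
#' @examples
#' call_phenotype(c(100, 100, 100), c(0, 30, 95))
#' @export
call_phenotype <- function(gfp_count, nongfp_count,
                           lethal_cut = 0.1, semi_cut = 0.5) {
  abort_if(any(gfp_count < 0, na.rm = TRUE) || any(nongfp_count < 0, na.rm = TRUE),
           "progeny counts must be non-negative")
  abort_if(!(lethal_cut < semi_cut), "lethal_cut must be below semi_cut")
  n <- max(length(gfp_count), length(nongfp_count))
  gfp <- rep_len(as.numeric(gfp_count), n)
  non <- rep_len(as.numeric(nongfp_count), n)
  out <- rep(NA_character_, n)
  invalid <- is.na(gfp) | is.na(non) | gfp == 0
  out[invalid] <- "invalid"
  r <- non / gfp
  out[!invalid & r < lethal_cut] <- "lethal"
  out[!invalid & r >= lethal_cut & r < semi_cut] <- "semi-lethal"
  out[!invalid & r >= semi_cut] <- "non-lethal"
  out
}

#' Merge semi-lethal calls into lethal
#'
#' @param calls Character vector of phenotype calls.
#' @return The vector with `semi-lethal` recoded to `lethal`.
#' @export
merge_semi_lethal <- function(calls) {
  calls[calls == "semi-lethal"] <- "lethal"
  calls
}

#' Filter KK-library landing-site artifacts
#'
#' KK lines carry the RNAi construct at the 30B3 landing site, but a
#' fraction also carry an insertion at the 40D3 (tio) site, which itself
#' causes pupal lethality with constitutive drivers and so confounds
#' lethality calls. Lines with a 40D3 insertion (alone or together with
#' 30B3) are excluded from lethality inference unless they were recombined
#' back to 30B3-only.
#'
#' @param lines Data.frame with logical (or 0/1) columns `has_30B3`,
#'   `has_40D3` and optionally `recombined`. Rows with `NA` insertion flags
#'   are routed to `uncalled`.
#' @return A list: `usable`, `excluded`, `uncalled` (row subsets of
#'   `lines`), and `summary` with counts and percentages of dual-site and
#'   40D3-only lines.
#' @examples
#' lines <- data.frame(has_30B3 = c(TRUE, TRUE), has_40D3 = c(FALSE, TRUE),
#'                     recombined = c(FALSE, FALSE))
#' genotype_filter(lines)$summary
#' @export
genotype_filter <- function(lines) {
  abort_if(!all(c("has_30B3", "has_40D3") %in% names(lines)),
           "lines need has_30B3 and has_40D3 columns")
  h30 <- as.logical(lines$has_30B3)
  h40 <- as.logical(lines$has_40D3)
  rec <- if ("recombined" %in% names(lines)) {
    r <- as.logical(lines$recombined)
    r[is.na(r)] <- FALSE
    r
  } else rep(FALSE, nrow(lines))

  uncalled <- is.na(h30) | is.na(h40)
  excluded <- !uncalled & h40 & !rec
  usable <- !uncalled & !excluded

  n <- nrow(lines)
  n_dual <- sum(!uncalled & h30 & h40)
  n_40_only <- sum(!uncalled & !h30 & h40)
  summary <- list(
    n = n,
    n_dual_site = n_dual,
    n_40d3_only = n_40_only,
    pct_dual_site = if (n > 0) 100 * n_dual / n else NA_real_,
    pct_40d3_only = if (n > 0) 100 * n_40_only / n else NA_real_,
    n_usable = sum(usable), n_excluded = sum(excluded),
    n_uncalled = sum(uncalled)
  )
  list(usable = lines[usable, , drop = FALSE],
       excluded = lines[excluded, , drop = FALSE],
       uncalled = lines[uncalled, , drop = FALSE],
       summary = summary)
}

#' Gene-level lethality call from multiple lines
#'
#' A gene is called `lethal` if any usable line targeting it is lethal
#' (after merging semi-lethal); `non-lethal` if at least one usable line was
#' scored and none is lethal; `uncalled` if every line is invalid. The
#' any-lethal rule is the conservative choice when insufficient knockdown
#' drives false negatives.
#'
#' @param gene_id Character vector of gene ids, one per line.
#' @param calls Character vector of line-level calls
#'   (`lethal`/`semi-lethal`/`non-lethal`/`invalid`).
#' @return Named character vector of per-gene calls.
#' @export
gene_level_calls <- function(gene_id, calls) {
  abort_if(length(gene_id) != length(calls), "gene_id and calls lengths differ")
  calls <- merge_semi_lethal(calls)
  genes <- unique(as.character(gene_id))
  out <- vapply(genes, function(g) {
    cl <- calls[gene_id == g]
    cl <- cl[cl %in% c("lethal", "non-lethal")]
    if (length(cl) == 0) "uncalled" else if (any(cl == "lethal")) "lethal" else "non-lethal"
  }, character(1))
  out
}

#' Agreement between two screens
#'
#' Compares binary lethal/non-lethal calls for the genes shared by two
#' screens and summarizes agreement.
#'
#' @param calls_a,calls_b Named character vectors of per-gene calls
#'   (`lethal`/`non-lethal`); names are gene ids. Only the intersection of
#'   names is compared.
#' @return A list of class `concordance_summary`: `n_pairs`,
#'   `n_both_lethal`, `n_both_nonlethal`, `n_discordant`,
#'   `percent_agreement`, and `detail` (discordant counts by direction).
#' @examples
#' a <- c(g1 = "lethal", g2 = "non-lethal", g3 = "lethal")
#' b <- c(g1 = "lethal", g2 = "lethal", g3 = "lethal")
#' concordance(a, b)$percent_agreement
#' @export
concordance <- function(calls_a, calls_b) {
  shared <- intersect(names(calls_a), names(calls_b))
  abort_if(length(shared) == 0, "no shared gene ids between the two screens")
  a <- calls_a[shared]
  b <- calls_b[shared]
  ok <- a %in% c("lethal", "non-lethal") & b %in% c("lethal", "non-lethal")
  a <- a[ok]; b <- b[ok]
  abort_if(length(a) == 0, "no comparable (lethal/non-lethal) shared calls")
  n_ll <- sum(a == "lethal" & b == "lethal")
  n_nn <- sum(a == "non-lethal" & b == "non-lethal")
  n_pairs <- length(a)
  out <- list(
    n_pairs = n_pairs,
    n_both_lethal = n_ll,
    n_both_nonlethal = n_nn,
    n_discordant = n_pairs - n_ll - n_nn,
    percent_agreement = 100 * (n_ll + n_nn) / n_pairs,
    detail = list(
      a_lethal_b_nonlethal = sum(a == "lethal" & b == "non-lethal"),
      a_nonlethal_b_lethal = sum(a == "non-lethal" & b == "lethal"),
      n_lethal_a = sum(a == "lethal"),
      n_lethal_b = sum(b == "lethal")
    )
  )
  class(out) <- "concordance_summary"
  out
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("concordance: %d pairs, %d both-lethal, %d both-non-lethal, %d discordant (%.1f%% agreement)\n",
              x$n_pairs, x$n_both_lethal, x$n_both_nonlethal, x$n_discordant,
              x$percent_agreement))
  invisible(x)
}

#' Build a concordance summary from pre-tabulated counts
#'
#' Convenience for published tallies where only the counts are available.
#'
#' @param n_pairs Total number of shared genes compared.
#' @param n_both_lethal,n_both_nonlethal Agreement counts.
#' @return A `concordance_summary`.
#' @export
concordance_from_counts <- function(n_pairs, n_both_lethal, n_both_nonlethal) {
  abort_if(!is_count(n_pairs) || !is_count(n_both_lethal) || !is_count(n_both_nonlethal),
           "counts must be non-negative integers")
  abort_if(n_both_lethal + n_both_nonlethal > n_pairs,
           "agreement counts exceed n_pairs")
  out <- list(
    n_pairs = as.integer(n_pairs),
    n_both_lethal = as.integer(n_both_lethal),
    n_both_nonlethal = as.integer(n_both_nonlethal),
    n_discordant = as.integer(n_pairs - n_both_lethal - n_both_nonlethal),
    percent_agreement = 100 * (n_both_lethal + n_both_nonlethal) / n_pairs,
    detail = NULL
  )
  class(out) <- "concordance_summary"
  out
}
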