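#' Assign a gene's origination branch by single-gain (Dollo) parsimony
#'
#' Given a presence/absence/unknown call per species and a rooted species
#' tree, places the gene's origin on the branch immediately above the most
#' recent common ancestor of all species where the gene is present. This is
#' the Dollo reconstruction: exactly one gain, with absences inside the
#' clade explained by losses. Species called `unknown` (e.g. unassembled
#' regions) are treated as missing data and ignored in the MRCA computation,
#' not as absences.
#'
#' @param presence Named vector of per-species calls. Accepted encodings:
#'   character `"present"`/`"absent"`/`"unknown"`, or numeric `1`/`0`/`NA`.
#'   Names must be leaf labels of `tree`; species not listed are `unknown`.
#' @param tree A [species_tree()].
#' @return A list with `branch` (integer index on the root-to-focal path,
#'   0 = root/oldest, K = focal terminal branch), `branch_label`, and
#'   `n_losses` (minimal number of loss events needed inside the gain clade,
#'   counting each maximal lost subtree once; `unknown` leaves are free).
#' @examples
#' tr <- species_tree(default_drosophila_tree(), "D_melanogaster")
#' assign_origination_branch(
#'   c(D_melanogaster = 1, D_simulans = 1, D_sechellia = 1), tr)$branch
#' @export
assign_origination_branch <- function(presence, tree) {
  abort_if(!inherits(tree, "species_tree"), "tree must be a species_tree")
  calls <- normalize_presence(presence)
  abort_if(length(calls) == 0L, "empty presence call set")
  unknown_species <- setdiff(names(calls), tree$phylo$tip.label)
  abort_if(length(unknown_species) > 0,
           "species not in tree: %s", paste(unknown_species, collapse = ", "))
  focal_call <- calls[tree$focal]
  abort_if(is.na(focal_call) || focal_call != "present",
           "focal species '%s' must be called present for a datable gene",
           tree$focal)

  present <- names(calls)[calls == "present" & !is.na(calls)]
  branch <- min(tree$attachment[present])

  list(branch = as.integer(branch),
       branch_label = tree$branch_labels[branch + 1L],
       n_losses = count_dollo_losses(tree, branch, calls))
}

normalize_presence <- function(presence) {
  abort_if(is.null(names(presence)) || any(!nzchar(names(presence))),
           "presence calls must be named by species")
  if (is.numeric(presence) || is.logical(presence)) {
    bad <- !is.na(presence) & !(presence %in% c(0, 1))
    abort_if(any(bad), "numeric presence values must be 1, 0 or NA")
    out <- ifelse(is.na(presence), "unknown", ifelse(presence == 1, "present", "absent"))
  } else {
    out <- as.character(presence)
    out[is.na(out)] <- "unknown"
    bad <- !(out %in% c("present", "absent", "unknown"))
    abort_if(any(bad), "presence calls must be present/absent/unknown (or 1/0/NA)")
  }
  names(out) <- names(presence)
  out
}

# Minimal number of loss events below the gain node: each maximal subtree
# with no `present` leaf and at least one `absent` leaf costs one loss.
# `unknown` leaves can be assumed either state, so subtrees of only-unknown
# leaves cost nothing.
count_dollo_losses <- function(tree, branch, calls) {
  phy <- tree$phylo
  gain_node <- tree$path_nodes[branch + 1L]
  tips <- descendant_tips(phy, gain_node)
  state <- rep("unknown", length(phy$tip.label))
  state[match(names(calls), phy$tip.label)] <- calls

  kids <- split(phy$edge[, 2], phy$edge[, 1])
  ntip <- length(phy$tip.label)
  # postorder accumulation of (has_present, has_absent, losses)
  rec <- function(node) {
    if (node <= ntip) {
      return(list(p = state[node] == "present", a = state[node] == "absent", l = 0))
    }
    ch <- lapply(kids[[as.character(node)]], rec)
    p <- any(vapply(ch, `[[`, logical(1), "p"))
    a <- any(vapply(ch, `[[`, logical(1), "a"))
    l <- sum(vapply(ch, function(c.) {
      if (c.[["p"]]) c.[["l"]] else as.numeric(c.[["a"]])
    }, numeric(1)))
    list(p = p, a = a, l = l)
  }
  r <- rec(gain_node)
  if (!r[["p"]]) return(as.integer(r[["a"]]))  # gain node itself lost (degenerate)
  as.integer(r[["l"]])
}

#' Date every gene in a presence/absence matrix
#'
#' Applies [assign_origination_branch()] row-wise to a gene-by-species
#' presence matrix and joins optional origination-mechanism annotations.
#'
#' @param presence A data.frame with a `gene_id` column and one column per
#'   species with values 1/0/NA, or a numeric matrix with gene rownames.
#' @param tree A [species_tree()].
#' @param annotations Optional data.frame with columns `gene_id` and
#'   `mechanism` (values `DNA-duplication`, `RNA-duplication`, `orphan`;
#'   anything else is recoded `unknown`).
#' @return A data.frame: gene_id, branch, branch_label, mechanism,
#'   n_inferred_losses.
#' @export
assign_gene_ages <- function(presence, tree, annotations = NULL) {
  if (is.data.frame(presence)) {
    abort_if(!("gene_id" %in% names(presence)), "presence table needs a gene_id column")
    ids <- as.character(presence$gene_id)
    mat <- as.matrix(presence[setdiff(names(presence), "gene_id")])
    rownames(mat) <- ids
  } else {
    mat <- as.matrix(presence)
    abort_if(is.null(rownames(mat)), "presence matrix needs gene rownames")
    ids <- rownames(mat)
  }
  abort_if(anyDuplicated(ids) > 0, "duplicate gene ids in presence input")
  storage.mode(mat) <- "double"

  res <- lapply(seq_along(ids), function(i) {
    assign_origination_branch(mat[i, ], tree)
  })
  out <- data.frame(
    gene_id = ids,
    branch = vapply(res, `[[`, integer(1), "branch"),
    branch_label = vapply(res, `[[`, character(1), "branch_label"),
    mechanism = "unknown",
    n_inferred_losses = vapply(res, `[[`, integer(1), "n_losses"),
    stringsAsFactors = FALSE
  )
  if (!is.null(annotations)) {
    abort_if(!all(c("gene_id", "mechanism") %in% names(annotations)),
             "annotations need gene_id and mechanism columns")
    m <- match(out$gene_id, annotations$gene_id)
    mech <- as.character(annotations$mechanism[m])
    mech[is.na(mech) | !(mech %in% c("DNA-duplication", "RNA-duplication", "orphan"))] <- "unknown"
    out$mechanism <- mech
  }
  out
}

#' Tabulate lethality by origination branch
#'
#' @param ages Data.frame from [assign_gene_ages()] (needs `gene_id`,
#'   `branch`).
#' @param phenotypes Named character vector (or data.frame with `gene_id`,
#'   `call`) of per-gene calls, `lethal`/`non-lethal`. Every phenotyped gene
#'   must have an age record.
#' @return Data.frame with one row per observed branch: branch, n, n_lethal,
#'   proportion.
#' @export
tabulate_by_branch <- function(ages, phenotypes) {
  ph <- normalize_phenotypes(phenotypes)
  missing <- setdiff(names(ph), ages$gene_id)
  abort_if(length(missing) > 0,
           "phenotype for gene(s) with no age record: %s",
           paste(utils::head(missing, 5), collapse = ", "))
  key <- ages$branch[match(names(ph), ages$gene_id)]
  tabulate_calls(key, ph, "branch")
}

#' Tabulate lethality by origination mechanism
#'
#' Genes with mechanism `unknown` are excluded from the three-category table
#' and counted separately.
#'
#' @inheritParams tabulate_by_branch
#' @return A list: `table` (mechanism, n, n_lethal, proportion over the
#'   three mechanism categories) and `n_unknown`.
#' @export
tabulate_by_mechanism <- function(ages, phenotypes) {
  ph <- normalize_phenotypes(phenotypes)
  missing <- setdiff(names(ph), ages$gene_id)
  abort_if(length(missing) > 0,
           "phenotype for gene(s) with no age record: %s",
           paste(utils::head(missing, 5), collapse = ", "))
  mech <- ages$mechanism[match(names(ph), ages$gene_id)]
  known <- mech %in% c("DNA-duplication", "RNA-duplication", "orphan")
  list(table = tabulate_calls(mech[known], ph[known], "mechanism"),
       n_unknown = sum(!known))
}

normalize_phenotypes <- function(phenotypes) {
  if (is.data.frame(phenotypes)) {
    abort_if(!all(c("gene_id", "call") %in% names(phenotypes)),
             "phenotype table needs gene_id and call columns")
    ph <- stats::setNames(as.character(phenotypes$call), phenotypes$gene_id)
  } else {
    ph <- as.character(phenotypes)
    names(ph) <- names(phenotypes)
  }
  abort_if(is.null(names(ph)), "phenotypes must be named by gene id")
  bad <- !(ph %in% c("lethal", "non-lethal"))
  abort_if(any(bad), "phenotype calls must be lethal/non-lethal")
  ph
}

tabulate_calls <- function(key, calls, key_name) {
  groups <- sort(unique(key))
  n <- vapply(groups, function(g) sum(key == g), numeric(1))
  nl <- vapply(groups, function(g) sum(key == g & calls == "lethal"), numeric(1))
  out <- data.frame(key = groups, n = as.integer(n), n_lethal = as.integer(nl),
                    proportion = nl / n, stringsAsFactors = FALSE)
  names(out)[1] <- key_name
  out
}
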