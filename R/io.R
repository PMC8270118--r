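# Table and tree readers/writers. All tabular interchange is
# tab-separated, headered, LF or CRLF, with NA encoded as the literal "NA".

read_tsv_checked <- function(path, required, name) {
  abort_if(!file.exists(path), "%s file not found: %s", name, path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  abort_if(length(missing) > 0, "%s (%s) is missing required column(s): %s",
           name, path, paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a screen line table
#'
#' Expected columns: `line_id`, `gene_id`, `library`, `has_30B3`,
#' `has_40D3`, `recombined`, `driver`, `gfp_count`, `nongfp_count`,
#' `phenotype` (phenotype may be blank/NA where counts are given).
#'
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_screen_tsv <- function(path) {
  df <- read_tsv_checked(path, c("line_id", "gene_id", "library", "has_30B3",
                                 "has_40D3", "recombined", "gfp_count",
                                 "nongfp_count"), "screen table")
  for (col in c("has_30B3", "has_40D3", "recombined")) {
    df[[col]] <- as.logical(df[[col]])
  }
  abort_if(anyDuplicated(df$line_id) > 0, "duplicate line ids in %s", path)
  df
}

#' Read a gene-by-species presence/absence table
#'
#' First column `gene_id`; remaining columns are species with values in
#' {1, 0, NA}.
#'
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_presence_tsv <- function(path) {
  df <- read_tsv_checked(path, "gene_id", "presence matrix")
  abort_if(ncol(df) < 2, "presence matrix has no species columns")
  abort_if(anyDuplicated(df$gene_id) > 0, "duplicate gene ids in %s", path)
  for (col in setdiff(names(df), "gene_id")) {
    v <- df[[col]]
    bad <- !is.na(v) & !(v %in% c(0, 1))
    abort_if(any(bad), "presence column '%s' has values outside {1, 0, NA}", col)
    df[[col]] <- as.numeric(v)
  }
  df
}

#' Read a long-format qPCR Ct table
#'
#' Expected columns: `sample_id`, `line_id`, `gene_id`, `gene_role`,
#' `condition`, `replicate`, `ct` (and optionally `library`).
#'
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_qpcr_tsv <- function(path) {
  read_tsv_checked(path, c("line_id", "gene_id", "gene_role", "condition",
                           "replicate", "ct"), "qPCR table")
}

#' Read an old-gene essentiality pool table
#'
#' Expected columns: `gene_id`, `essential` (0/1 or TRUE/FALSE).
#'
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_pool_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "essential"), "old-gene pool")
  df$essential <- as.logical(df$essential)
  abort_if(anyNA(df$essential), "pool essential flags must be 0/1")
  df
}

#' Read a gene annotation table
#'
#' Expected columns: `gene_id`, `mechanism`; optional `paralog_id`,
#' `similarity`.
#'
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_annotations_tsv <- function(path) {
  read_tsv_checked(path, c("gene_id", "mechanism"), "annotation table")
}

#' Write a synthetic bundle to a directory
#'
#' Writes the species tree as newick, all tables as headered TSVs, and the
#' configuration as YAML. Two calls with the same bundle are byte-identical.
#'
#' @param bundle A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  abort_if(!inherits(bundle, "synthetic_bundle"), "bundle must be a synthetic_bundle")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(bundle$tree, file.path(dir, "tree.nwk"))
  write_tsv(bundle$presence, file.path(dir, "presence.tsv"))
  write_tsv(bundle$annotations, file.path(dir, "annotations.tsv"))
  for (nm in names(bundle$screens)) {
    write_tsv(bundle$screens[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  if (!is.null(bundle$qpcr)) write_tsv(bundle$qpcr, file.path(dir, "qpcr.tsv"))
  if (!is.null(bundle$knockout)) write_tsv(bundle$knockout, file.path(dir, "knockout.tsv"))
  write_tsv(bundle$truth_genes, file.path(dir, "truth_genes.tsv"))
  write_tsv(bundle$truth_lines, file.path(dir, "truth_lines.tsv"))
  cfg <- bundle$config
  cfg_list <- cfg[setdiff(names(cfg), "tree")]
  cfg_list$focal <- bundle$focal
  cfg_list$efficiency_params <- lapply(cfg_list$efficiency_params, as.list)
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return A list with `tree` (newick string), `focal`, `presence`,
#'   `annotations`, `screens`, `qpcr`, `knockout`, `truth_genes`,
#'   `truth_lines`, `config` (as a plain list, when present).
#' @export
read_bundle <- function(dir) {
  abort_if(!dir.exists(dir), "bundle directory not found: %s", dir)
  tree <- readLines(file.path(dir, "tree.nwk"), warn = FALSE)[1]
  screens <- list()
  for (f in sort(list.files(dir, pattern = "^screen_\\d+\\.tsv$"))) {
    screens[[sub("\\.tsv$", "", f)]] <- read_screen_tsv(file.path(dir, f))
  }
  maybe <- function(f, reader) {
    p <- file.path(dir, f)
    if (file.exists(p)) reader(p) else NULL
  }
  cfg_path <- file.path(dir, "config.yaml")
  list(
    tree = tree,
    focal = if (file.exists(cfg_path)) yaml::read_yaml(cfg_path)$focal else NULL,
    presence = read_presence_tsv(file.path(dir, "presence.tsv")),
    annotations = maybe("annotations.tsv", read_annotations_tsv),
    screens = screens,
    qpcr = maybe("qpcr.tsv", read_qpcr_tsv),
    knockout = maybe("knockout.tsv", function(p)
      read_tsv_checked(p, c("mutant_gene", "assay_gene", "gene_role",
                            "condition", "replicate", "expression"),
                       "knockout table")),
    truth_genes = maybe("truth_genes.tsv", function(p)
      read_tsv_checked(p, c("gene_id", "branch", "essential"), "gene truth")),
    truth_lines = maybe("truth_lines.tsv", function(p)
      read_tsv_checked(p, c("line_id", "true_efficiency"), "line truth")),
    config = if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  )
}
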