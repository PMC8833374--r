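#' Construct a transcription-factor target-gene set
#'
#' A pathway's activity is read out from the mRNA levels of a selected set of
#' target genes of its associated transcription factor (typically 20-30
#' genes).  Each gene carries the direction of regulation expected when the
#' pathway is active: `"up"` (transcription induced) or `"down"` (repressed).
#'
#' @param pathway_name Single character label for the pathway.
#' @param gene_id Character vector of unique gene symbols.
#' @param direction Character vector, one of `"up"`/`"down"` per gene.
#'   Recycled if length 1.
#' @param source Free-text provenance note.
#' @return An object of class `target_gene_set`: a list with elements
#'   `pathway_name`, `genes` (data.frame with columns `gene_id`,
#'   `direction`) and `source`.
#' @export
target_gene_set <- function(pathway_name, gene_id, direction = "up",
                            source = "") {
  stopifnot(is.character(pathway_name), length(pathway_name) == 1L,
            nzchar(pathway_name))
  gene_id <- as.character(gene_id)
  if (length(gene_id) < 1L)
    stop("a target gene set needs at least one gene", call. = FALSE)
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids in gene set '", pathway_name, "': ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "),
         call. = FALSE)
  direction <- rep_len(as.character(direction), length(gene_id))
  if (!all(direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down' for every gene", call. = FALSE)
  structure(
    list(pathway_name = pathway_name,
         genes = data.frame(gene_id = gene_id, direction = direction,
                            stringsAsFactors = FALSE),
         source = source),
    class = "target_gene_set")
}

#' @export
print.target_gene_set <- function(x, ...) {
  n_dn <- sum(x$genes$direction == "down")
  cat(sprintf("<target_gene_set> %s: %d genes (%d down-regulated)\n",
              x$pathway_name, nrow(x$genes), n_dn))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.  Down-regulated target
#' genes are encoded with a `|dn` suffix (`"GENE|dn"`); bare tokens are
#' up-regulated targets.  Comment lines starting with `#` are ignored.
#'
#' @param path Path to a GMT file.
#' @return Named list of [target_gene_set] objects (names = pathway names).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, " in '", path,
           "': expected at least 3 tab-separated fields", call. = FALSE)
    tokens <- fields[-(1:2)]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0L)
      stop("malformed GMT line ", i, " in '", path, "': empty gene list",
           call. = FALSE)
    down <- grepl("\\|dn$", tokens)
    target_gene_set(pathway_name = fields[[1]],
                    gene_id = sub("\\|dn$", "", tokens),
                    direction = ifelse(down, "down", "up"),
                    source = fields[[2]])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "pathway_name")
  if (anyDuplicated(names(sets)))
    stop("duplicate pathway names in GMT file '", path, "'", call. = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' Inverse of [read_gmt()]; down-regulated genes get the `|dn` suffix.
#'
#' @param gene_sets List of [target_gene_set] objects.
#' @param path Output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(gene_sets, function(gs) {
    tok <- ifelse(gs$genes$direction == "down",
                  paste0(gs$genes$gene_id, "|dn"), gs$genes$gene_id)
    desc <- if (nzchar(gs$source)) gs$source else "na"
    paste(c(gs$pathway_name, desc, tok), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
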