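# Taxonomy tree construction and iTOL-style annotation layer export.

#' Build a Newick taxonomy tree from lineages
#'
#' The tree is the prefix tree over the ordered rank paths: lineages sharing
#' a rank prefix share the corresponding internal node (polytomies allowed),
#' leaves are proteome ids, internal nodes carry their rank labels, there
#' are no branch lengths, and siblings are ordered lexicographically so the
#' output is byte-stable.
#'
#' @param lineages Tibble with `proteome_id` and ordered rank columns.
#' @param ranks Rank column names, root-most first (default: every column
#'   except `proteome_id`/`taxid`/`name`).
#' @return A Newick string (single leaf: `"id;"`).
#' @export
build_tree <- function(lineages, ranks = NULL) {
  if (nrow(lineages) < 1) {
    stop("need at least one lineage", call. = FALSE)
  }
  if (is.null(ranks)) {
    ranks <- setdiff(names(lineages), c("proteome_id", "taxid", "name"))
  }
  if (anyDuplicated(lineages$proteome_id)) {
    dup <- unique(lineages$proteome_id[duplicated(lineages$proteome_id)])
    stop("conflicting lineages for: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  emit <- function(rows, depth) {
    if (depth > length(ranks)) {
      return(sort(rows$proteome_id))
    }
    labels <- rows[[ranks[depth]]]
    parts <- vapply(sort(unique(labels)), function(lab) {
      children <- emit(rows[labels == lab, , drop = FALSE], depth + 1)
      if (length(children) == 1) {
        # unary ranks add no structure: collapse the node onto its child
        children
      } else {
        paste0("(", paste(children, collapse = ","), ")", lab)
      }
    }, character(1))
    parts
  }
  top <- emit(lineages, 1)
  if (length(top) == 1) {
    paste0(top, ";")
  } else {
    paste0("(", paste(top, collapse = ","), ");")
  }
}

#' Leaf labels of a Newick string
#'
#' @param newick Newick string.
#' @return Character vector of tip labels.
#' @export
newick_leaves <- function(newick) {
  if (!grepl("\\(", newick)) {
    return(sub(";$", "", newick))
  }
  ape::read.tree(text = newick)$tip.label
}

#' Annotation layer specification
#'
#' @param layer_id File-name stem of the layer.
#' @param kind `"BAR"` (non-negative numeric values) or `"BINARY"` (0/1).
#' @param column Column of the pathway matrix supplying the per-leaf value.
#' @param color Hex color for the iTOL legend.
#' @param label Dataset label (default `layer_id`).
#' @return A layer spec list.
#' @export
layer_spec <- function(layer_id, kind = c("BAR", "BINARY"), column,
                       color = "#1f77b4", label = layer_id) {
  kind <- match.arg(kind)
  list(layer_id = layer_id, kind = kind, column = column, color = color,
       label = label)
}

#' Default annotation layers for a pathway matrix
#'
#' Proteome size as a bar layer plus one binary layer per pathway boolean,
#' mirroring the distribution-pattern figure layers (sizes, enzymes,
#' pathways) as files.
#'
#' @param matrix A `pathway_matrix`.
#' @return List of [layer_spec()]s.
#' @export
default_layer_specs <- function(matrix) {
  path_cols <- grep("^pathway_", names(matrix), value = TRUE)
  palette <- rep(c("#d62728", "#1f77b4", "#2ca02c", "#ff7f0e", "#9467bd",
                   "#8c564b"), length.out = length(path_cols))
  c(list(layer_spec("proteome_size", "BAR", "proteome_size",
                    color = "#d62728", label = "Proteome size")),
    lapply(seq_along(path_cols), function(i) {
      layer_spec(path_cols[i], "BINARY", path_cols[i], color = palette[i],
                 label = sub("^pathway_", "", path_cols[i]))
    }))
}

format_layer_value <- function(v) {
  ifelse(v == round(v), sprintf("%d", as.integer(round(v))),
         sprintf("%g", v))
}

#' Export iTOL annotation layers for a tree
#'
#' Writes one plain-text dataset file per layer in the iTOL simple-bar /
#' binary dialect (`SEPARATOR COMMA`, `DATASET_LABEL`, `COLOR`, then a
#' `DATA` block of `leaf,value` lines). Every matrix row must be a tree
#' leaf.
#'
#' @param matrix A `pathway_matrix`.
#' @param newick Newick string from [build_tree()].
#' @param specs List of [layer_spec()]s (default [default_layer_specs()]).
#' @param dir Output directory.
#' @return Tibble `layer_id`, `kind`, `path` (one row per file), invisibly.
#' @export
export_layers <- function(matrix, newick, specs = default_layer_specs(matrix),
                          dir = ".") {
  leaves <- newick_leaves(newick)
  missing <- setdiff(matrix$proteome_id, leaves)
  if (length(missing) > 0) {
    stop("matrix rows missing from tree: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(specs, function(sp) {
    vals <- matrix[[sp$column]]
    if (sp$kind == "BINARY") {
      vals <- as.integer(as.logical(vals))
    } else if (any(vals < 0)) {
      stop("BAR layer ", sp$layer_id, " has negative values", call. = FALSE)
    }
    header <- c(
      if (sp$kind == "BAR") "DATASET_SIMPLEBAR" else "DATASET_BINARY",
      "SEPARATOR COMMA",
      paste0("DATASET_LABEL,", sp$label),
      paste0("COLOR,", sp$color),
      if (sp$kind == "BINARY") c("FIELD_SHAPES,1",
                                 paste0("FIELD_LABELS,", sp$label),
                                 paste0("FIELD_COLORS,", sp$color)),
      "DATA"
    )
    path <- file.path(dir, paste0(sp$layer_id, ".txt"))
    writeLines(c(header, paste(matrix$proteome_id,
                               format_layer_value(vals), sep = ",")),
               path)
    path
  }, character(1))
  invisible(tibble::tibble(
    layer_id = vapply(specs, `[[`, character(1), "layer_id"),
    kind = vapply(specs, `[[`, character(1), "kind"),
    path = paths))
}
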