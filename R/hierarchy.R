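#' Cancer-category label hierarchies
#'
#' A label hierarchy is a rooted tree of cancer categories (OncoTree-style).
#' Depth-1 nodes are the "major" categories; deeper nodes are subcategories.
#' The hierarchy drives branch-classifier layout, score propagation, and the
#' hierarchical evaluation metrics.
#'
#' Internally a `too_hierarchy` is a list with a `nodes` tibble
#' (`code`, `name`, `parent`, `depth`, `reportable`), the `root` code, and a
#' precomputed child map. Build one from a data frame with [as_hierarchy()],
#' read one from JSON with [load_hierarchy()], or use the bundled
#' [default_hierarchy()].
#'
#' @name too_hierarchy
NULL

#' Marker used for cancer-of-unknown-primary submissions
#' @return The string `"CUP"`.
#' @export
cup_marker <- function() "CUP"

#' Marker returned for diagnoses that cannot be mapped to a hierarchy code
#' @return The string `"<UNMAPPED>"`.
#' @export
unmapped_marker <- function() "<UNMAPPED>"

too_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "too_error"))
}

#' Build a validated label hierarchy from a node table
#'
#' @param nodes A data frame with columns `code`, `name`, `parent`
#'   (`NA` for the root) and `reportable` (logical). `name` defaults to
#'   `code` and `reportable` to `TRUE` for non-root nodes if absent.
#'
#' @details Validation rejects duplicate codes
#'   (`too_error_duplicate_code`), references to absent parents
#'   (`too_error_orphan_parent`), zero or multiple roots
#'   (`too_error_root`), and cycles / disconnected components
#'   (`too_error_cycle`). Depth is computed from the parent map.
#'
#' @return A `too_hierarchy` object.
#' @export
#' @examples
#' h <- as_hierarchy(data.frame(
#'   code = c("ROOT", "A", "B", "A1", "A2"),
#'   parent = c(NA, "ROOT", "ROOT", "A", "A")
#' ))
#' n_major(h)
as_hierarchy <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("code", "parent") %in% names(nodes)))
  if (!"name" %in% names(nodes)) nodes$name <- nodes$code
  if (!"reportable" %in% names(nodes)) nodes$reportable <- TRUE
  nodes$code <- as.character(nodes$code)
  nodes$parent <- as.character(nodes$parent)

  if (anyDuplicated(nodes$code)) {
    too_abort(
      paste0("duplicate node code(s): ",
             paste(unique(nodes$code[duplicated(nodes$code)]), collapse = ", ")),
      "too_error_duplicate_code")
  }
  is_root <- is.na(nodes$parent)
  if (sum(is_root) == 0L) {
    too_abort("no root node (exactly one node must have a missing parent)",
              "too_error_root")
  }
  if (sum(is_root) > 1L) {
    too_abort(paste0("multiple root nodes: ",
                     paste(nodes$code[is_root], collapse = ", ")),
              "too_error_root")
  }
  orphans <- setdiff(nodes$parent[!is_root], nodes$code)
  if (length(orphans)) {
    too_abort(paste0("parent code(s) not defined in the hierarchy: ",
                     paste(orphans, collapse = ", ")),
              "too_error_orphan_parent")
  }

  root <- nodes$code[is_root]
  # breadth-first depth assignment; any node never reached sits on a cycle
  # (or in a component detached from the root)
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$code)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- nodes$code[!is.na(nodes$parent) & nodes$parent %in% frontier]
    depth[nxt] <- depth[nodes$parent[match(nxt, nodes$code)]] + 1L
    frontier <- nxt
  }
  if (anyNA(depth)) {
    too_abort(paste0("cycle or unreachable node(s): ",
                     paste(names(depth)[is.na(depth)], collapse = ", ")),
              "too_error_cycle")
  }

  nodes$depth <- unname(depth[nodes$code])
  nodes$reportable <- as.logical(nodes$reportable) & nodes$depth > 0L
  nodes <- dplyr::arrange(nodes, .data$depth, .data$code)
  nodes <- nodes[, c("code", "name", "parent", "depth", "reportable")]

  children <- split(nodes$code[!is.na(nodes$parent)],
                    nodes$parent[!is.na(nodes$parent)])
  children <- lapply(children, sort)

  structure(
    list(nodes = nodes, root = root, children = children),
    class = "too_hierarchy")
}

#' @export
print.too_hierarchy <- function(x, ...) {
  cat(sprintf(
    "<too_hierarchy> %d labels (%d major, %d subcategories), %d branches\n",
    sum(x$nodes$depth > 0), n_major(x),
    sum(x$nodes$depth > 1), nrow(branches(x))))
  invisible(x)
}

#' Read a label hierarchy from its JSON definition
#'
#' The document is a JSON array of objects `{code, name, parent, reportable}`;
#' the root has `parent: null`.
#'
#' @param path Path to the JSON document.
#' @return A `too_hierarchy`.
#' @seealso [write_hierarchy()] for the inverse.
#' @export
load_hierarchy <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  doc$parent[vapply(doc$parent, is.null, logical(1))] <- NA_character_
  as_hierarchy(doc)
}

#' Serialize a hierarchy to JSON
#'
#' @param h A `too_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly. `load_hierarchy(write_hierarchy(h, p))`
#'   reproduces the node set, parent map and branch list exactly.
#' @export
write_hierarchy <- function(h, path) {
  jsonlite::write_json(
    h$nodes[, c("code", "name", "parent", "reportable")],
    path, auto_unbox = TRUE, na = "null", pretty = TRUE)
  invisible(path)
}

#' Number of major (depth-1) categories
#' @param h A `too_hierarchy`.
#' @return Integer count.
#' @export
n_major <- function(h) sum(h$nodes$depth == 1L)

#' Reportable label codes
#' @param h A `too_hierarchy`.
#' @return Character vector of codes with `reportable = TRUE`.
#' @export
reportable_labels <- function(h) h$nodes$code[h$nodes$reportable]

#' Terminal (leaf) label codes
#' @param h A `too_hierarchy`.
#' @return Character vector of codes without children.
#' @export
terminal_labels <- function(h) {
  setdiff(h$nodes$code[h$nodes$depth > 0L], names(h$children))
}

hierarchy_children <- function(h, code) {
  ch <- h$children[[code]]
  if (is.null(ch)) character(0) else ch
}

assert_code <- function(h, code) {
  bad <- setdiff(code, h$nodes$code)
  if (length(bad)) {
    too_abort(paste0("unknown hierarchy code(s): ", paste(bad, collapse = ", ")),
              "too_error_unknown_code")
  }
}

#' Path from the depth-1 ancestor down to a node, root excluded
#'
#' The root is the broadest category and is never counted in hierarchical
#' metrics, so it is excluded from all paths.
#'
#' @param h A `too_hierarchy`.
#' @param code A node code.
#' @return Character vector ordered major-first; `character(0)` for the root.
#' @export
path_to_root <- function(h, code) {
  assert_code(h, code)
  parent <- stats::setNames(h$nodes$parent, h$nodes$code)
  path <- character(0)
  while (!is.na(parent[[code]])) {
    path <- c(code, path)
    code <- parent[[code]]
  }
  path
}

#' All descendants of a node
#' @param h A `too_hierarchy`.
#' @param code A node code.
#' @return Character vector of strict descendants (possibly empty).
#' @export
descendants <- function(h, code) {
  assert_code(h, code)
  out <- character(0)
  frontier <- hierarchy_children(h, code)
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, hierarchy_children, h = h),
                       use.names = FALSE)
  }
  out
}

#' Branch specifications of a hierarchy
#'
#' One branch per internal node with at least two children; each branch gets
#' its own classifier network. Internal nodes with a single child produce no
#' branch: the child deterministically inherits the parent score during
#' propagation (a softmax over one label is constant 1).
#'
#' @param h A `too_hierarchy`.
#' @return A tibble with `parent_code` and a `child_codes` list-column
#'   (children in lexicographic order); root branch first, remaining branches
#'   in lexicographic `parent_code` order.
#' @export
branches <- function(h) {
  parents <- names(h$children)[vapply(h$children, length, integer(1)) >= 2L]
  parents <- c(intersect(h$root, parents),
               sort(setdiff(parents, h$root)))
  tibble::tibble(
    parent_code = parents,
    child_codes = lapply(parents, hierarchy_children, h = h))
}

#' Map submitted diagnoses to hierarchy codes
#'
#' @param h A `too_hierarchy`.
#' @param submitted Character vector of submitted diagnosis strings or codes.
#' @param mapping Optional data frame `(submitted_string, code)`. Matching is
#'   case-insensitive on the submitted string.
#' @return Character vector: a hierarchy code, [cup_marker()] for CUP
#'   submissions, or [unmapped_marker()]. No input is ever dropped.
#' @export
map_diagnosis <- function(h, submitted, mapping = NULL) {
  submitted <- as.character(submitted)
  out <- rep(unmapped_marker(), length(submitted))
  norm <- stringr::str_trim(toupper(submitted))
  out[norm == cup_marker() | norm == "UNKNOWN PRIMARY"] <- cup_marker()
  if (!is.null(mapping)) {
    i <- match(norm, stringr::str_trim(toupper(mapping$submitted_string)))
    hit <- !is.na(i) & out == unmapped_marker()
    out[hit] <- mapping$code[i[hit]]
  }
  direct <- out == unmapped_marker() & submitted %in% h$nodes$code
  out[direct] <- submitted[direct]
  bad <- setdiff(out, c(h$nodes$code, cup_marker(), unmapped_marker()))
  if (length(bad)) {
    too_abort(paste0("mapping table targets unknown code(s): ",
                     paste(bad, collapse = ", ")),
              "too_error_unknown_code")
  }
  out
}

#' The bundled default hierarchy
#'
#' A 90-label configuration with 26 major cancer categories and 64
#' subcategories (20 classifier branches). Category names are realistic but
#' membership is illustrative: every algorithm in the package is
#' topology-generic and tests construct their own small hierarchies.
#'
#' @return A `too_hierarchy` with 90 reportable labels.
#' @export
default_hierarchy <- function() {
  majors <- list(
    BREAST    = c("IDC", "ILC", "MUCINOUS", "METAPLASTIC"),
    LUNG_NSC  = c("LUAD", "LUSC", "LCLC", "ADENOSQ"),
    SARCOMA   = c("LEIOMYO", "LIPO", "OSTEO", "SYNOVIAL"),
    LYMPHOMA  = c("DLBCL", "FOLLICULAR", "HODGKIN", "MARGINAL"),
    GLIOMA    = c("GBM", "ASTRO", "OLIGO", "EPEND"),
    KIDNEY    = c("CLEARCELL", "PAPILLARY", "CHROMOPHOBE", "COLLECTING"),
    OVARY     = c("HGSOC", "ENDOMETRIOID", "CLEARCELL", "MUCINOUS"),
    SKIN_MEL  = c("CUTANEOUS", "ACRAL", "MUCOSAL", "UVEAL"),
    STOMACH   = c("INTESTINAL", "DIFFUSE", "GIST"),
    ESOPHAGUS = c("ADENO", "SCC", "GEJ"),
    LIVER     = c("HCC", "FIBROLAMELLAR", "HEPATOBLASTOMA"),
    BILIARY   = c("INTRAHEPATIC", "EXTRAHEPATIC", "GALLBLADDER"),
    UTERUS    = c("ENDOMETRIOID", "SEROUS", "CARCINOSARCOMA"),
    HNSC      = c("ORAL", "LARYNX", "OROPHARYNX"),
    THYROID   = c("PAPILLARY", "FOLLICULAR", "MEDULLARY"),
    NEUROEND  = c("SMALLCELL", "LARGECELL", "CARCINOID"),
    GERMCELL  = c("SEMINOMA", "NONSEMINOMA", "TERATOMA"),
    PANCREAS  = c("DUCTAL", "ACINAR", "NEUROEND"),
    COLORECT  = c("COLON", "RECTUM"),
    LUNG_SC   = character(0),
    BLADDER   = character(0),
    PROSTATE  = character(0),
    CERVIX    = character(0),
    MYELOMA   = character(0),
    MESOTHELIOMA = character(0),
    LEUKEMIA  = character(0))
  rows <- list(data.frame(code = "TUMOR_ROOT", name = "All tumors",
                          parent = NA_character_, reportable = FALSE))
  for (m in names(majors)) {
    rows[[length(rows) + 1L]] <- data.frame(
      code = m, name = m, parent = "TUMOR_ROOT", reportable = TRUE)
    subs <- majors[[m]]
    if (length(subs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        code = paste(m, subs, sep = "_"),
        name = paste(m, subs, sep = " "),
        parent = m, reportable = TRUE)
    }
  }
  as_hierarchy(do.call(rbind, rows))
}
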