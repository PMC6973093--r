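#' Read and validate a rooted, time-calibrated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the structural
#' contract every downstream analysis relies on: a single rooted tree, branch
#' lengths present on every edge (time units, e.g. Myr), unique tip labels,
#' and no negative branch lengths. Zero-length terminal branches are permitted
#' (time trees often contain them as artifacts) but raise a warning because
#' they contribute zero variance and zero path-wise rate.
#'
#' @param path Path to a newick file. The first tree in the file is used.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  .check_balanced_parens(txt, path)
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("malformed newick in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed newick in '", path, "': no tree parsed")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_phylogeny(tree)
  tree
}

# Reports the character offset of the first unbalanced parenthesis so that a
# truncated newick fails with a usable location; deeper grammar errors are
# delegated to ape's parser.
.check_balanced_parens <- function(txt, path) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick in '", path,
             "': unmatched ')' at character offset ", i, call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("malformed newick in '", path, "': ", depth,
         " unclosed '(' (first at offset ",
         which(chars == "(")[1], ")", call. = FALSE)
}

#' Validate the phylogeny invariants assumed by the rate models
#'
#' Checks: rooted binary-or-polytomous topology with exactly one root, branch
#' lengths present and non-negative, unique tip labels. Returns the tree
#' invisibly so it can be used in a pipeline.
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; time-calibrated branch lengths are required")
  if (anyNA(tree$edge.length))
    stop("tree has missing branch lengths on ", sum(is.na(tree$edge.length)),
         " edge(s); no silent default is applied")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s): ",
         paste(signif(tree$edge.length[tree$edge.length < 0], 3), collapse = ", "))
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  }
  n <- length(tree$tip.label)
  # every non-root node has exactly one parent; exactly one root
  child_counts <- tabulate(tree$edge[, 2], nbins = n + tree$Nnode)
  if (any(child_counts > 1)) stop("node with multiple parents: not a tree")
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1) stop("expected exactly one root, found ", length(roots))
  term <- tree$edge[, 2] <= n
  if (any(tree$edge.length[term] == 0))
    warning(sum(tree$edge.length[term] == 0),
            " zero-length terminal branch(es): these tips contribute zero ",
            "residual variance and zero path-wise rate")
  invisible(tree)
}

#' Write a phylogeny to a newick file
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Default column mapping and controlled vocabularies for trait tables
#'
#' The trait table is a CSV with one row per species carrying raw testes mass
#' and body mass in grams, a taxonomic class, and (optionally) a social mating
#' system. `trait_schema()` names the columns so files with alternative
#' headers can be read, and declares the accepted category tokens.
#'
#' Mating-system tokens are normalized to three canonical codes:
#' `M` (monogamy), `PG` (polygyny) and `PA` (polyandry and polygynandry,
#' pooled because both imply several males per female and hence high sperm
#' competition).
#'
#' @param species,testes,body,class,mating Column names in the file.
#' @param classes Allowed taxonomic class levels.
#' @return A list used by [read_trait_table()].
#' @export
trait_schema <- function(species = "species",
                         testes = "testes_mass_g",
                         body = "body_mass_g",
                         class = "class",
                         mating = "mating_system",
                         classes = c("fish", "frogs", "birds", "mammals", "reptiles")) {
  list(species = species, testes = testes, body = body, class = class,
       mating = mating, classes = classes)
}

# canonical mating-system codes and accepted synonyms
.mating_tokens <- c(
  monogamy = "M", monogamous = "M", m = "M",
  polygyny = "PG", polygynous = "PG", pg = "PG",
  polyandry = "PA", polyandrous = "PA", polygynandry = "PA",
  polygynandrous = "PA", "polyandry/polygynandry" = "PA",
  polyandry_polygynandry = "PA", pa = "PA",
  # pre-merged category used where monogamy and polygyny cannot be separated
  "m+pg" = "M+PG", "monogamy+polygyny" = "M+PG"
)

#' Read a species trait table
#'
#' Reads a CSV of species trait data, log10-transforms the masses, normalizes
#' the mating-system tokens, and rejects rows that cannot enter the analysis
#' (non-positive or missing masses). Rejected rows are reported in the
#' `"rejected"` attribute, never dropped silently.
#'
#' @param path CSV file with a header.
#' @param schema Column mapping from [trait_schema()].
#' @return A `data.frame` with columns `species`, `testes` (log10 g), `body`
#'   (log10 g), `class` (factor) and `mating` (factor, `NA` allowed), plus a
#'   `"rejected"` attribute (data.frame of dropped rows and reasons).
#' @export
read_trait_table <- function(path, schema = trait_schema()) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(schema$species, schema$testes, schema$body, schema$class)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  has_mating <- schema$mating %in% names(raw)

  species <- gsub("\\s+", "_", trimws(as.character(raw[[schema$species]])))
  if (anyDuplicated(species))
    stop("duplicate species label(s): ",
         paste(unique(species[duplicated(species)]), collapse = ", "))

  testes_raw <- suppressWarnings(as.numeric(raw[[schema$testes]]))
  body_raw <- suppressWarnings(as.numeric(raw[[schema$body]]))
  bad <- !is.finite(testes_raw) | !is.finite(body_raw) |
    testes_raw <= 0 | body_raw <= 0
  rejected <- data.frame(
    species = species[bad],
    reason = ifelse(!is.finite(testes_raw[bad]) | !is.finite(body_raw[bad]),
                    "non-numeric or missing mass", "non-positive mass"),
    stringsAsFactors = FALSE
  )

  cls <- as.character(raw[[schema$class]])
  unknown_cls <- setdiff(unique(cls[!bad]), schema$classes)
  if (length(unknown_cls))
    stop("unknown taxonomic class token(s): ",
         paste(unknown_cls, collapse = ", "),
         " (allowed: ", paste(schema$classes, collapse = ", "), ")")

  if (has_mating) {
    ms_raw <- trimws(as.character(raw[[schema$mating]]))
    ms_raw[ms_raw == ""] <- NA_character_
    key <- tolower(ms_raw)
    ms <- unname(.mating_tokens[key])
    bad_ms <- !is.na(ms_raw) & is.na(ms)
    if (any(bad_ms))
      stop("unknown mating-system token(s) in rows: ",
           paste(which(bad_ms), collapse = ", "), " (",
           paste(unique(ms_raw[bad_ms]), collapse = ", "), ")")
  } else {
    ms <- rep(NA_character_, nrow(raw))
  }

  out <- data.frame(
    species = species[!bad],
    testes = log10(testes_raw[!bad]),
    body = log10(body_raw[!bad]),
    class = factor(cls[!bad], levels = schema$classes),
    mating = factor(ms[!bad], levels = c("M", "PG", "PA", "M+PG")),
    stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- rejected
  out
}

.normalize_label <- function(x) tolower(gsub("\\s+", "_", trimws(x)))

#' Match a trait table to a tree and prune both to the shared species
#'
#' Labels are matched exactly after whitespace-to-underscore normalization and
#' case folding (no fuzzy matching, for reproducibility). The tree is pruned
#' to the intersection; internal nodes left with a single child are collapsed
#' with their branch lengths summed, so every retained tip keeps its original
#' root-to-tip path length. The table is reordered to the pruned tree's tip
#' order.
#'
#' @param tree A `phylo` object.
#' @param table A trait table from [read_trait_table()] (any data.frame with a
#'   `species` column works).
#' @return A list with elements `tree` and `table`.
#' @export
match_and_prune <- function(tree, table) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(table),
            "species" %in% names(table))
  tip_norm <- .normalize_label(tree$tip.label)
  tab_norm <- .normalize_label(table$species)
  if (anyDuplicated(tip_norm)) stop("tip labels collide after normalization")
  if (anyDuplicated(tab_norm)) stop("species labels collide after normalization")
  shared <- intersect(tip_norm, tab_norm)
  if (length(shared) == 0) stop("no species shared between tree and trait table")
  keep_tips <- tree$tip.label[tip_norm %in% shared]
  if (length(keep_tips) == length(tree$tip.label)) {
    pruned <- tree
  } else {
    pruned <- ape::keep.tip(tree, keep_tips)
    # keep.tip re-roots at the retained tips' MRCA; the basal path removed is
    # common to every retained tip and is preserved as the root edge so that
    # total root-to-tip path lengths never change
    deficit <- unname(tip_depths(tree)[keep_tips[1]] -
                        tip_depths(pruned)[keep_tips[1]])
    if (deficit > 1e-12)
      pruned$root.edge <- (pruned$root.edge %||% 0) + deficit
  }
  idx <- match(.normalize_label(pruned$tip.label), tab_norm)
  out_tab <- table[idx, , drop = FALSE]
  rownames(out_tab) <- NULL
  # keep the table keyed by the tree's spelling of each label
  out_tab$species <- pruned$tip.label
  list(tree = pruned, table = out_tab)
}

#' Root-to-tip path lengths
#'
#' Depth of every tip below the root in branch-length units (including the
#' root edge, if the tree carries one from pruning), in `tree$tip.label`
#' order. Used throughout for covariance checks and path-wise rate
#' bookkeeping.
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector of tip depths.
#' @export
tip_depths <- function(tree) {
  n <- length(tree$tip.label)
  depth <- numeric(n + tree$Nnode)
  # preorder guarantees parents are visited before children
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    e <- tr$edge[k, ]
    depth[e[2]] <- depth[e[1]] + tr$edge.length[k]
  }
  stats::setNames(depth[seq_len(n)] + (tree$root.edge %||% 0), tree$tip.label)
}
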