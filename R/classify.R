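## Cobamide biosynthesis category and dependence classification from
## per-genome gene presence, with pathway-subsection completeness scoring.

#' Default cobamide biosynthesis pathway model
#'
#' Encodes the de novo cobamide biosynthesis pathway as ordered subsections
#' (tetrapyrrole precursor synthesis, aerobic and anaerobic corrin ring
#' synthesis, nucleotide loop synthesis, lower ligand synthesis) with the
#' canonical cob/cbi gene complement, the aerobic/anaerobic orthologue
#' pairs (either member satisfies a requirement), the nucleotide-loop
#' salvage gene set (cobQ/cbiP, cobD/cbiB, cobP/cobU, cobS), the seven
#' cobamide-dependent enzyme families tracked by the pipeline, and the
#' marker panel used for metagenomic producer calls (11 markers; the
#' producer-call default is the 10 markers excluding bluB, since known
#' producers of nonbenzimidazolyl cobamides lack bluB). The gene sets are
#' documented defaults and fully replaceable.
#'
#' @return A list of class \code{pathway_model} with elements
#'   \code{subsections}, \code{orthologue_pairs}, \code{salvage_genes},
#'   \code{dependent_enzymes}, \code{marker_genes} (producer-call panel) and
#'   \code{all_markers}.
#' @export
default_pathway_model <- function() {
  subsections <- list(
    tetrapyrrole_precursor = c("hemA", "hemB", "hemC", "hemD", "cysG"),
    corrin_ring_aerobic = c("cobI", "cobG", "cobJ", "cobM", "cobF",
                            "cobK", "cobL", "cobH", "cobB", "cobN"),
    corrin_ring_anaerobic = c("cbiL", "cbiG", "cbiH", "cbiF", "cbiD",
                              "cbiJ", "cbiE", "cbiC", "cbiA", "cbiK"),
    nucleotide_loop = c("cobO", "cobQ", "cbiP", "cobD", "cbiB",
                        "cobP", "cobU", "cobS", "cobC"),
    lower_ligand = c("bluB", "cobT")
  )
  orthologue_pairs <- c(cobI = "cbiL", cobJ = "cbiH", cobM = "cbiF",
                        cobK = "cbiJ", cobL = "cbiE", cobH = "cbiC",
                        cobB = "cbiA", cobN = "cbiK",
                        cobQ = "cbiP", cobD = "cbiB", cobP = "cobU")
  model <- structure(list(
    subsections = subsections,
    orthologue_pairs = orthologue_pairs,
    salvage_genes = list(c("cobQ", "cbiP"), c("cobD", "cbiB"),
                         c("cobP", "cobU"), "cobS"),
    dependent_enzymes = c("nrdJ", "metH", "mutA", "eutB", "pduC",
                          "oraE", "queG"),
    marker_genes = c("cobI", "cobJ", "cobM", "cobH", "cobB",
                     "cobN", "cobQ", "cobD", "cobU", "cobS"),
    all_markers = c("cobI", "cobJ", "cobM", "cobH", "cobB",
                    "cobN", "cobQ", "cobD", "cobU", "cobS", "bluB")
  ), class = "pathway_model")
  validate_pathway_model(model)
}

validate_pathway_model <- function(model) {
  genes <- unlist(model$subsections, use.names = FALSE)
  if (anyDuplicated(genes))
    stopf("gene(s) assigned to more than one subsection: %s",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (any(lengths(model$subsections) == 0L))
    stopf("empty pathway subsection in model")
  salv <- unlist(model$salvage_genes, use.names = FALSE)
  if (!all(salv %in% model$subsections$nucleotide_loop))
    stopf("salvage genes must be nucleotide-loop genes")
  model
}

#' Category decision rules
#'
#' Thresholds for assigning the cobamide biosynthesis category. A genome is
#' a producer when its corrin-ring completeness (best of the aerobic and
#' anaerobic routes, orthologue-aware) and its nucleotide-loop completeness
#' both meet their minima; otherwise a precursor salvager when enough of
#' the salvage gene set is present; otherwise a nonproducer.
#'
#' @param producer_corrin_min Minimum corrin-ring completeness (default 0.5).
#' @param producer_loop_min Minimum nucleotide-loop completeness
#'   (default 0.5).
#' @param salvager_min_salvage_genes Minimum number of salvage gene slots
#'   present (default 3 of the 4).
#' @return A list of class \code{category_rules}.
#' @export
category_rules <- function(producer_corrin_min = 0.5,
                           producer_loop_min = 0.5,
                           salvager_min_salvage_genes = 3L) {
  structure(list(producer_corrin_min = producer_corrin_min,
                 producer_loop_min = producer_loop_min,
                 salvager_min_salvage_genes =
                   as.integer(salvager_min_salvage_genes)),
            class = "category_rules")
}

## A gene requirement is satisfied by the gene itself or its aerobic/
## anaerobic orthologue partner.
.expand_orthologues <- function(genes, model) {
  pairs <- model$orthologue_pairs
  unique(c(genes,
           names(pairs)[pairs %in% genes],     # anaerobic member seen
           unname(pairs[names(pairs) %in% genes])))  # aerobic member seen
}

## Slot completeness: collapse orthologue pair members within `slot_genes`
## into single requirements, count satisfied slots.
.slot_completeness <- function(genes, slot_genes, model) {
  have <- .expand_orthologues(genes, model)
  pairs <- model$orthologue_pairs
  canonical <- ifelse(slot_genes %in% pairs,
                      names(pairs)[match(slot_genes, pairs)], slot_genes)
  slots <- split(slot_genes, canonical)
  mean(vapply(slots, function(s) any(s %in% have), logical(1)))
}

#' Pathway-subsection completeness
#'
#' Fraction of each pathway subsection's genes present in a genome. The
#' combined \code{corrin_ring} entry is the better of the aerobic and
#' anaerobic routes after mapping orthologue pairs, and \code{nucleotide_loop}
#' additionally honours within-loop orthologue pairs (cobQ/cbiP, cobD/cbiB,
#' cobP/cobU count as single requirements) in the reported
#' \code{nucleotide_loop_slots} entry.
#'
#' @param genes Character vector (set) of gene symbols present.
#' @param model A [default_pathway_model()]-style model.
#' @return Named numeric vector: one fraction per subsection plus
#'   \code{corrin_ring} and \code{nucleotide_loop_slots}.
#' @export
subsection_completeness <- function(genes, model = default_pathway_model()) {
  validate_pathway_model(model)
  plain <- vapply(model$subsections,
                  function(s) length(intersect(genes, s)) / length(s),
                  numeric(1))
  corrin <- max(
    .slot_completeness(genes, model$subsections$corrin_ring_aerobic, model),
    .slot_completeness(genes, model$subsections$corrin_ring_anaerobic, model))
  loop <- .slot_completeness(genes, model$subsections$nucleotide_loop, model)
  c(plain, corrin_ring = corrin, nucleotide_loop_slots = loop)
}

#' Cobamide biosynthesis category
#'
#' Assigns producer / salvager / nonproducer from a genome's gene set. The
#' decision and the rule that fired are returned together, so every call is
#' traceable.
#'
#' @param genes Character vector of gene symbols present in the genome.
#' @param model Pathway model.
#' @param rules [category_rules()].
#' @return list(category, trace, completeness).
#' @export
classify_biosynthesis <- function(genes, model = default_pathway_model(),
                                  rules = category_rules()) {
  comp <- subsection_completeness(genes, model)
  have <- .expand_orthologues(genes, model)
  n_salvage <- sum(vapply(model$salvage_genes,
                          function(s) any(s %in% have), logical(1)))
  if (comp[["corrin_ring"]] >= rules$producer_corrin_min &&
      comp[["nucleotide_loop_slots"]] >= rules$producer_loop_min) {
    cat <- "producer"
    trace <- sprintf(
      "corrin_ring %.2f >= %.2f and nucleotide_loop %.2f >= %.2f",
      comp[["corrin_ring"]], rules$producer_corrin_min,
      comp[["nucleotide_loop_slots"]], rules$producer_loop_min)
  } else if (n_salvage >= rules$salvager_min_salvage_genes) {
    cat <- "salvager"
    trace <- sprintf("%d/%d salvage gene slots present (>= %d)",
                     n_salvage, length(model$salvage_genes),
                     rules$salvager_min_salvage_genes)
  } else {
    cat <- "nonproducer"
    trace <- sprintf(
      "corrin_ring %.2f, nucleotide_loop %.2f, salvage slots %d: no rule met",
      comp[["corrin_ring"]], comp[["nucleotide_loop_slots"]], n_salvage)
  }
  list(category = cat, trace = trace, completeness = comp)
}

#' Cobamide dependence
#'
#' A genome is cobamide dependent when it encodes at least one of the seven
#' tracked cobamide-dependent enzyme families.
#'
#' @param genes Gene set of the genome.
#' @param model Pathway model (supplies \code{dependent_enzymes}).
#' @return list(dependent = logical, found = character vector).
#' @export
classify_dependence <- function(genes, model = default_pathway_model()) {
  found <- sort(intersect(genes, model$dependent_enzymes))
  list(dependent = length(found) > 0L, found = found)
}

#' Annotate a set of genomes
#'
#' Applies category and dependence classification to every genome in a gene
#' table (as returned by [read_gene_table()]), producing one annotation row
#' per genome.
#'
#' @param gene_sets Named list genome_id -> character vector of genes.
#' @param model Pathway model.
#' @param rules [category_rules()].
#' @param association Optional named character vector genome_id ->
#'   \code{"host"}/\code{"environment"}.
#' @return data.frame with columns \code{genome_id}, \code{category},
#'   \code{dependent}, \code{dependent_enzymes_found},
#'   \code{benzimidazolyl_capable}, \code{corrin_ring},
#'   \code{nucleotide_loop}, \code{association}; decision traces attached
#'   as attribute \code{"traces"}.
#' @export
annotate_genomes <- function(gene_sets, model = default_pathway_model(),
                             rules = category_rules(), association = NULL) {
  rows <- lapply(names(gene_sets), function(g) {
    genes <- gene_sets[[g]]
    cls <- classify_biosynthesis(genes, model, rules)
    dep <- classify_dependence(genes, model)
    data.frame(
      genome_id = g, category = cls$category, dependent = dep$dependent,
      dependent_enzymes_found = paste(dep$found, collapse = ","),
      benzimidazolyl_capable = "bluB" %in% genes,
      corrin_ring = cls$completeness[["corrin_ring"]],
      nucleotide_loop = cls$completeness[["nucleotide_loop_slots"]],
      association = if (is.null(association)) NA_character_
                    else unname(association[g]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "traces") <- setNames(
    vapply(names(gene_sets),
           function(g) classify_biosynthesis(gene_sets[[g]], model,
                                             rules)$trace, ""),
    names(gene_sets))
  out
}

#' Compare a genome metric between association groups
#'
#' Two-sided Mann-Whitney U test of a numeric per-genome metric (genome
#' length, gene cluster count, ...) between host- and environment-associated
#' genomes. Exact for small tie-free groups, normal approximation with tie
#' correction otherwise (the behaviour of \code{wilcox.test}).
#'
#' @param annotations Annotation data.frame from [annotate_genomes()] with a
#'   non-missing \code{association} column.
#' @param metric Named numeric vector genome_id -> metric value.
#' @return list with group medians, the U statistic (first group) and the
#'   two-sided p-value.
#' @export
compare_groups <- function(annotations, metric) {
  assert_cols(annotations, c("genome_id", "association"), "annotations")
  x <- metric[annotations$genome_id[annotations$association == "host"]]
  y <- metric[annotations$genome_id[annotations$association == "environment"]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stopf("both association groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(median_host = median(x), median_environment = median(y),
       n_host = length(x), n_environment = length(y),
       U = unname(wt$statistic), p.value = wt$p.value,
       method = wt$method)
}
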