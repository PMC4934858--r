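# Metabolic model container, readers/writers, and GPR utilities.

#' Construct a metabolic model
#'
#' Builds the constraint-based model object used throughout the package: a
#' stoichiometric network with flux bounds, one biomass objective reaction and
#' gene-protein-reaction (GPR) rules. Fluxes are specific rates in
#' mmol h^-1 gDCW^-1 (the biomass reaction carries the growth rate, h^-1).
#'
#' @param metabolites Tibble/data frame with columns `id` and logical
#'   `external`. External metabolites appear in exchange reactions only.
#' @param reactions Tibble/data frame with columns `id`, `stoichiometry`
#'   (list column of named numeric vectors, metabolite -> coefficient),
#'   `lower_bound`, `upper_bound` (mmol h^-1 gDCW^-1) and `gpr`
#'   (character Boolean rule over gene ids, `""` for none).
#' @param objective Reaction id of the (single) biomass objective.
#' @param genes Optional tibble with columns `gene_id`, `length_bp`, `copies`
#'   (copies of that subunit in the enzyme complex; default 1).
#' @param id Model identifier string.
#'
#' @return An object of class `ddd_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective,
                            genes = NULL, id = "model") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(genes)) {
    genes <- tibble::tibble(gene_id = character(), length_bp = integer(),
                            copies = integer())
  } else {
    genes <- tibble::as_tibble(genes)
    if (!"copies" %in% names(genes)) genes$copies <- 1L
  }
  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         objective = objective, genes = genes),
    class = "ddd_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: all referenced metabolites are declared,
#' `lower_bound <= upper_bound` everywhere, and the objective names exactly one
#' declared reaction.
#'
#' @param model A `ddd_model`.
#' @return The model, invisibly; aborts with an informative error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "ddd_model"))
  rxn <- model$reactions
  met_ids <- model$metabolites$id
  if (anyDuplicated(met_ids)) stop("duplicated metabolite ids", call. = FALSE)
  if (anyDuplicated(rxn$id)) stop("duplicated reaction ids", call. = FALSE)
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoichiometry[[i]]
    if (length(s) == 0L) stop("reaction '", rxn$id[i], "' has empty stoichiometry",
                              call. = FALSE)
    unknown <- setdiff(names(s), met_ids)
    if (length(unknown) > 0L) {
      stop("reaction '", rxn$id[i], "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
    stop("lower bound exceeds upper bound for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(model$objective) != 1L || !model$objective %in% rxn$id) {
    stop("objective must name exactly one declared reaction", call. = FALSE)
  }
  invisible(model)
}

#' @export
print.ddd_model <- function(x, ...) {
  cat("<ddd_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      " (", sum(x$metabolites$external), " external)\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions),
      " (", length(exchange_reactions(x)), " exchange)\n", sep = "")
  cat("  objective:   ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' All metabolites (including external ones) are balanced; exchange reactions
#' are the only boundary across which mass enters or leaves, so their bounds
#' constrain the network.
#'
#' @param model A `ddd_model`.
#' @param internal_only Drop rows of external metabolites (default `FALSE`).
#' @return Numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model, internal_only = FALSE) {
  mets <- model$metabolites$id
  S <- matrix(0, nrow = length(mets), ncol = nrow(model$reactions),
              dimnames = list(mets, model$reactions$id))
  for (i in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoichiometry[[i]]
    S[names(s), i] <- s
  }
  if (internal_only) S <- S[!model$metabolites$external, , drop = FALSE]
  S
}

#' Exchange reactions of a model
#'
#' A reaction touching exactly one metabolite is an exchange; by the BiGG sign
#' convention negative flux is uptake, positive flux secretion.
#'
#' @param model A `ddd_model`.
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  n_met <- vapply(model$reactions$stoichiometry, length, integer(1))
  model$reactions$id[n_met == 1L]
}

#' Set flux bounds on a model
#'
#' @param model A `ddd_model`.
#' @param reaction Reaction id(s).
#' @param lower,upper Optional replacement bounds, recycled along `reaction`.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction, lower = NULL, upper = NULL) {
  idx <- match(reaction, model$reactions$id)
  if (anyNA(idx)) stop("unknown reaction(s): ",
                       paste(reaction[is.na(idx)], collapse = ", "), call. = FALSE)
  if (!is.null(lower)) model$reactions$lower_bound[idx] <- rep_len(lower, length(idx))
  if (!is.null(upper)) model$reactions$upper_bound[idx] <- rep_len(upper, length(idx))
  validate_model(model)
  model
}

# ---- GPR parsing ------------------------------------------------------------

gpr_tokenize <- function(rule) {
  rule <- gsub("\\(", " ( ", rule)
  rule <- gsub("\\)", " ) ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# Recursive-descent parser for Boolean GPR rules; returns disjunctive normal
# form as a list of character vectors (each vector = one AND complex).
gpr_parse_expr <- function(toks, pos) {
  left <- gpr_parse_term(toks, pos)
  pos <- left$pos
  complexes <- left$complexes
  while (pos <= length(toks) && tolower(toks[pos]) %in% c("or", "|")) {
    rhs <- gpr_parse_term(toks, pos + 1L)
    complexes <- c(complexes, rhs$complexes)
    pos <- rhs$pos
  }
  list(complexes = complexes, pos = pos)
}

gpr_parse_term <- function(toks, pos) {
  left <- gpr_parse_factor(toks, pos)
  pos <- left$pos
  complexes <- left$complexes
  while (pos <= length(toks) && tolower(toks[pos]) %in% c("and", "&")) {
    rhs <- gpr_parse_factor(toks, pos + 1L)
    # distribute AND over the accumulated disjunction
    complexes <- unlist(lapply(complexes, function(a) {
      lapply(rhs$complexes, function(b) unique(c(a, b)))
    }), recursive = FALSE)
    pos <- rhs$pos
  }
  list(complexes = complexes, pos = pos)
}

gpr_parse_factor <- function(toks, pos) {
  if (pos > length(toks)) stop("malformed GPR rule: unexpected end", call. = FALSE)
  tok <- toks[pos]
  if (tok == "(") {
    inner <- gpr_parse_expr(toks, pos + 1L)
    if (inner$pos > length(toks) || toks[inner$pos] != ")") {
      stop("malformed GPR rule: unbalanced parentheses", call. = FALSE)
    }
    list(complexes = inner$complexes, pos = inner$pos + 1L)
  } else if (tolower(tok) %in% c("and", "or", "&", "|", ")")) {
    stop("malformed GPR rule near '", tok, "'", call. = FALSE)
  } else {
    list(complexes = list(tok), pos = pos + 1L)
  }
}

#' Isoenzyme complexes of a GPR rule
#'
#' Normalises a Boolean gene-protein-reaction rule to disjunctive normal form:
#' a list of gene sets, one per isoenzyme (alternative enzyme), each listing
#' the subunit genes that are jointly required.
#'
#' @param rule GPR rule string, e.g. `"(a and b) or c"`; `""`/`NA` for none.
#' @return List of character vectors (empty list for an empty rule).
#' @export
gpr_complexes <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(list())
  toks <- gpr_tokenize(rule)
  parsed <- gpr_parse_expr(toks, 1L)
  if (parsed$pos <= length(toks)) {
    stop("malformed GPR rule: trailing tokens from '", toks[parsed$pos], "'",
         call. = FALSE)
  }
  lapply(parsed$complexes, function(g) sort(unique(g)))
}

#' Enzyme set of a GPR rule
#'
#' The sorted set of all gene ids occurring in the rule, regardless of the
#' AND/OR tree shape. Reactions with identical enzyme sets use the same
#' enzymes (same isoenzymes and subunits) and are lumped together by
#' [lump_fluxes()].
#'
#' @param rule GPR rule string.
#' @return Sorted character vector of gene ids (length 0 for an empty rule).
#' @export
enzyme_set <- function(rule) {
  out <- unlist(gpr_complexes(rule))
  if (is.null(out)) character(0) else sort(unique(out))
}

#' Enzyme-set signature string
#'
#' Canonical single-string form of [enzyme_set()] for use as a grouping key;
#' `""` for reactions without genes (such reactions are never lumped with
#' gene-bearing reactions).
#'
#' @param rule GPR rule string (vectorised).
#' @return Character vector of signatures.
#' @export
enzyme_signature <- function(rule) {
  vapply(rule, function(r) paste(enzyme_set(r), collapse = "|"), character(1),
         USE.NAMES = FALSE)
}

# ---- gene lengths -----------------------------------------------------------

#' Apparent gene length of a multi-copy subunit
#'
#' Translation of an enzyme complex is assumed rate-limited by its largest
#' subunit. When the complex contains `copies` > 1 copies of that subunit,
#' ribosomes queue along the transcript at the interribosomal spacing, so the
#' effective template length becomes `length_bp + copies * spacing_bp`; a
#' single-copy subunit keeps its raw length.
#'
#' @param length_bp Raw gene length (bp, >= 1).
#' @param copies Copies of the subunit in the complex (>= 1, default 1).
#' @param spacing_bp Interribosomal spacing (bp, default 72).
#' @param add_single If `TRUE`, add `copies * spacing_bp` even when
#'   `copies == 1` (default `FALSE`).
#' @return Apparent gene length in bp (vectorised).
#' @examples
#' apparent_gene_length(2802, 12)  # 2-oxoglutarate dehydrogenase, sucA: 3666
#' @export
apparent_gene_length <- function(length_bp, copies = 1, spacing_bp = 72,
                                 add_single = FALSE) {
  if (any(length_bp < 1) || any(copies < 1)) {
    stop("length_bp and copies must be positive", call. = FALSE)
  }
  if (any(spacing_bp < 0)) stop("spacing_bp must be non-negative", call. = FALSE)
  add <- if (add_single) copies >= 1 else copies > 1
  length_bp + ifelse(add, copies * spacing_bp, 0)
}

#' Largest subunit of a reaction's enzyme
#'
#' Returns the gene with maximal raw length among the genes of a GPR rule
#' (ties broken by lexicographic gene id); used as the translation-rate
#' determining subunit.
#'
#' @param rule GPR rule string.
#' @param genes Tibble with `gene_id` and `length_bp` columns.
#' @return Gene id, or `NA_character_` for an empty rule.
#' @export
largest_subunit <- function(rule, genes) {
  ids <- enzyme_set(rule)
  if (length(ids) == 0L) return(NA_character_)
  idx <- match(ids, genes$gene_id)
  if (anyNA(idx)) {
    stop("no length information for gene(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  len <- genes$length_bp[idx]
  cand <- ids[len == max(len)]
  sort(cand)[1]
}

#' Read a gene information table
#'
#' @param path Tab-separated file with header `gene_id`, `length_bp` and
#'   optional `copies`.
#' @return Tibble with those columns (`copies` defaulting to 1).
#' @export
read_gene_info <- function(path) {
  info <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(info))) {
    stop("gene info table needs columns gene_id and length_bp", call. = FALSE)
  }
  if (!"copies" %in% names(info)) info$copies <- 1L
  if (any(info$length_bp < 1) || any(info$copies < 1)) {
    stop("gene lengths and copy numbers must be positive", call. = FALSE)
  }
  info
}

# ---- JSON dialect -----------------------------------------------------------

#' Read a metabolic model
#'
#' Reads BiGG-style JSON or SBML Level 3 (with the flux-balance-constraints
#' extension). The dialect is chosen by `format`, or from the file extension
#' when `format = "auto"`. Metabolites in an `e` compartment (or flagged
#' external) are treated as external; exchange reactions are auto-detected as
#' single-metabolite reactions.
#'
#' @param path File path.
#' @param format `"auto"`, `"json"` or `"sbml"`.
#' @return A `ddd_model`.
#' @export
read_metabolic_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Write a metabolic model
#'
#' @param model A `ddd_model`.
#' @param path Output path; dialect from `format` or the file extension.
#' @param format `"auto"`, `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_metabolic_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  validate_model(model)
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

known_json_fields <- list(
  metabolite = c("id", "compartment", "name", "notes", "annotation", "charge",
                 "formula"),
  reaction = c("id", "name", "metabolites", "lower_bound", "upper_bound",
               "gene_reaction_rule", "objective_coefficient", "subsystem",
               "notes", "annotation"))

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed model JSON in '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  for (field in c("metabolites", "reactions")) {
    if (is.null(doc[[field]])) {
      stop("model JSON lacks required field '", field, "'", call. = FALSE)
    }
  }
  unknown <- unique(unlist(lapply(doc$metabolites, function(m)
    setdiff(names(m), known_json_fields$metabolite))))
  unknown <- c(unknown, unique(unlist(lapply(doc$reactions, function(r)
    setdiff(names(r), known_json_fields$reaction)))))
  if (length(unknown) > 0L) {
    warning("ignoring unknown model JSON field(s): ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  mets <- tibble::tibble(
    id = vapply(doc$metabolites, function(m) m$id, character(1)),
    external = vapply(doc$metabolites, function(m)
      identical(m$compartment, "e"), logical(1)))
  rxns <- tibble::tibble(
    id = vapply(doc$reactions, function(r) r$id, character(1)),
    stoichiometry = lapply(doc$reactions, function(r) {
      s <- unlist(r$metabolites)
      if (is.null(s)) stop("reaction '", r$id, "' has no metabolites",
                           call. = FALSE)
      s
    }),
    lower_bound = vapply(doc$reactions, function(r)
      r$lower_bound %||% -1000, numeric(1)),
    upper_bound = vapply(doc$reactions, function(r)
      r$upper_bound %||% 1000, numeric(1)),
    gpr = vapply(doc$reactions, function(r)
      r$gene_reaction_rule %||% "", character(1)))
  obj_coef <- vapply(doc$reactions, function(r)
    r$objective_coefficient %||% 0, numeric(1))
  if (sum(obj_coef != 0) != 1L) {
    stop("model must declare exactly one objective reaction ",
         "(objective_coefficient != 0)", call. = FALSE)
  }
  genes <- NULL
  if (!is.null(doc$genes)) {
    genes <- tibble::tibble(
      gene_id = vapply(doc$genes, function(g) g$id, character(1)),
      length_bp = vapply(doc$genes, function(g)
        as.numeric(g$notes$length_bp %||% NA_real_), numeric(1)),
      copies = vapply(doc$genes, function(g)
        as.numeric(g$notes$copies %||% 1), numeric(1)))
    if (all(is.na(genes$length_bp))) genes <- NULL
  }
  metabolic_model(mets, rxns, objective = rxns$id[obj_coef != 0],
                  genes = genes, id = doc$id %||% "model")
}

write_model_json <- function(model, path) {
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      list(id = model$metabolites$id[i],
           compartment = if (model$metabolites$external[i]) "e" else "c")
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      list(id = r$id,
           metabolites = as.list(r$stoichiometry[[1]]),
           lower_bound = r$lower_bound,
           upper_bound = r$upper_bound,
           gene_reaction_rule = r$gpr,
           objective_coefficient = if (r$id == model$objective) 1 else 0)
    }),
    genes = if (nrow(model$genes) > 0L) {
      lapply(seq_len(nrow(model$genes)), function(i) {
        g <- model$genes[i, ]
        list(id = g$gene_id,
             notes = list(length_bp = g$length_bp, copies = g$copies))
      })
    } else list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# ---- SBML dialect (Level 3, fbc subset) ------------------------------------

sbml_ns <- c(
  s = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

sbml_id_encode <- function(x) {
  # SBML SIds must match [A-Za-z_][A-Za-z0-9_]*; BiGG-style ids may not
  x <- gsub("[^A-Za-z0-9_]", "__", x)
  ifelse(grepl("^[0-9]", x), paste0("x_", x), x)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  mod <- xml2::xml_find_first(doc, ".//s:model", sbml_ns)
  if (inherits(mod, "xml_missing")) stop("no <model> element in SBML file",
                                         call. = FALSE)
  params <- xml2::xml_find_all(mod, ".//s:listOfParameters/s:parameter", sbml_ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(mod, ".//s:listOfSpecies/s:species", sbml_ns)
  mets <- tibble::tibble(
    id = xml2::xml_attr(sp, "name"),
    external = xml2::xml_attr(sp, "compartment") == "e")
  sid2name <- stats::setNames(mets$id, xml2::xml_attr(sp, "id"))
  gps <- xml2::xml_find_all(mod, ".//fbc:listOfGeneProducts/fbc:geneProduct", sbml_ns)
  gid2label <- stats::setNames(xml2::xml_attr(gps, "fbc:label", ns = sbml_ns),
                               xml2::xml_attr(gps, "fbc:id", ns = sbml_ns))
  rx_nodes <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", sbml_ns)
  parse_refs <- function(rx, what, sign) {
    refs <- xml2::xml_find_all(rx, paste0("./s:", what, "/s:speciesReference"), sbml_ns)
    if (length(refs) == 0L) return(numeric(0))
    stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                    sid2name[xml2::xml_attr(refs, "species")])
  }
  gpr_from_node <- function(node) {
    assoc <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", sbml_ns)
    if (inherits(assoc, "xml_missing")) return("")
    render <- function(n) {
      nm <- xml2::xml_name(n)
      if (nm == "geneProductRef") {
        gid2label[[xml2::xml_attr(n, "geneProduct")]]
      } else if (nm %in% c("and", "or")) {
        kids <- xml2::xml_children(n)
        paste0("(", paste(vapply(kids, render, character(1)),
                          collapse = paste0(" ", nm, " ")), ")")
      } else {
        stop("unsupported GPR element <", nm, "> in SBML", call. = FALSE)
      }
    }
    kids <- xml2::xml_children(assoc)
    if (length(kids) != 1L) stop("malformed geneProductAssociation", call. = FALSE)
    out <- render(kids[[1]])
    sub("^\\((.*)\\)$", "\\1", out)
  }
  rxns <- tibble::tibble(
    id = xml2::xml_attr(rx_nodes, "name"),
    stoichiometry = lapply(rx_nodes, function(rx) {
      s <- c(parse_refs(rx, "listOfReactants", -1),
             parse_refs(rx, "listOfProducts", +1))
      s[order(names(s))]
    }),
    lower_bound = unname(pval[xml2::xml_attr(rx_nodes, "fbc:lowerFluxBound", ns = sbml_ns)]),
    upper_bound = unname(pval[xml2::xml_attr(rx_nodes, "fbc:upperFluxBound", ns = sbml_ns)]),
    gpr = vapply(rx_nodes, gpr_from_node, character(1)))
  obj_ref <- xml2::xml_find_first(
    mod, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    sbml_ns)
  if (inherits(obj_ref, "xml_missing")) {
    stop("SBML model lacks an fbc objective", call. = FALSE)
  }
  obj_sid <- xml2::xml_attr(obj_ref, "fbc:reaction", ns = sbml_ns)
  rid_by_sid <- stats::setNames(rxns$id, xml2::xml_attr(rx_nodes, "id"))
  genes <- NULL
  if (length(gps) > 0L) {
    len <- as.numeric(xml2::xml_attr(gps, "fbc:length_bp", ns = sbml_ns))
    cop <- as.numeric(xml2::xml_attr(gps, "fbc:copies", ns = sbml_ns))
    if (!all(is.na(len))) {
      genes <- tibble::tibble(gene_id = xml2::xml_attr(gps, "label"),
                              length_bp = len,
                              copies = ifelse(is.na(cop), 1, cop))
    }
  }
  metabolic_model(mets, rxns, objective = unname(rid_by_sid[obj_sid]),
                  genes = genes,
                  id = xml2::xml_attr(mod, "id") %||% "model")
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  met_sid <- stats::setNames(paste0("M_", sbml_id_encode(model$metabolites$id)),
                             model$metabolites$id)
  rxn_sid <- stats::setNames(paste0("R_", sbml_id_encode(model$reactions$id)),
                             model$reactions$id)
  all_genes <- sort(unique(unlist(lapply(model$reactions$gpr, enzyme_set))))
  gene_sid <- stats::setNames(paste0("G_", sbml_id_encode(all_genes)), all_genes)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', sbml_ns[["s"]], '" xmlns:fbc="', sbml_ns[["fbc"]],
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', sbml_id_encode(model$id), '" fbc:strict="true">'),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '      <compartment id="e" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    lines <- c(lines, paste0(
      '      <species id="', met_sid[[model$metabolites$id[i]]],
      '" name="', esc(model$metabolites$id[i]),
      '" compartment="', if (model$metabolites$external[i]) "e" else "c",
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>'))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (i in seq_len(nrow(model$reactions))) {
    rid <- rxn_sid[[model$reactions$id[i]]]
    lines <- c(lines,
      paste0('      <parameter id="', rid, '_lb" value="',
             format(model$reactions$lower_bound[i], digits = 17),
             '" constant="true"/>'),
      paste0('      <parameter id="', rid, '_ub" value="',
             format(model$reactions$upper_bound[i], digits = 17),
             '" constant="true"/>'))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  gpr_xml <- function(rule, indent) {
    cxs <- gpr_complexes(rule)
    pad <- strrep(" ", indent)
    ref <- function(g) paste0(pad, '  <fbc:geneProductRef fbc:geneProduct="',
                              gene_sid[[g]], '"/>')
    complex_xml <- function(cx, extra = 0) {
      p2 <- strrep(" ", indent + extra)
      if (length(cx) == 1L) {
        paste0(p2, '<fbc:geneProductRef fbc:geneProduct="', gene_sid[[cx]], '"/>')
      } else {
        c(paste0(p2, "<fbc:and>"),
          paste0(p2, '  <fbc:geneProductRef fbc:geneProduct="',
                 gene_sid[cx], '"/>'),
          paste0(p2, "</fbc:and>"))
      }
    }
    if (length(cxs) == 1L) {
      complex_xml(cxs[[1]])
    } else {
      c(paste0(pad, "<fbc:or>"),
        unlist(lapply(cxs, complex_xml, extra = 2)),
        paste0(pad, "</fbc:or>"))
    }
  }
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rid <- rxn_sid[[r$id]]
    s <- r$stoichiometry[[1]]
    s <- s[order(names(s))]
    lines <- c(lines, paste0(
      '      <reaction id="', rid, '" name="', esc(r$id),
      '" reversible="', tolower(r$lower_bound < 0),
      '" fast="false" fbc:lowerFluxBound="', rid, '_lb" fbc:upperFluxBound="',
      rid, '_ub">'))
    react <- s[s < 0]; prod <- s[s > 0]
    if (length(react) > 0L) {
      lines <- c(lines, '        <listOfReactants>',
        vapply(names(react), function(m) paste0(
          '          <speciesReference species="', met_sid[[m]],
          '" stoichiometry="', format(-react[[m]], digits = 17),
          '" constant="true"/>'), character(1)),
        '        </listOfReactants>')
    }
    if (length(prod) > 0L) {
      lines <- c(lines, '        <listOfProducts>',
        vapply(names(prod), function(m) paste0(
          '          <speciesReference species="', met_sid[[m]],
          '" stoichiometry="', format(prod[[m]], digits = 17),
          '" constant="true"/>'), character(1)),
        '        </listOfProducts>')
    }
    if (nzchar(r$gpr)) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 gpr_xml(r$gpr, 10), '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    paste0('          <fbc:fluxObjective fbc:reaction="',
           rxn_sid[[model$objective]], '" fbc:coefficient="1"/>'),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>')
  if (length(all_genes) > 0L) {
    gene_line <- function(g) {
      extra <- ""
      j <- match(g, model$genes$gene_id)
      if (!is.na(j)) {
        extra <- paste0(' fbc:length_bp="', model$genes$length_bp[j],
                        '" fbc:copies="', model$genes$copies[j], '"')
      }
      paste0('      <fbc:geneProduct fbc:id="', gene_sid[[g]], '" fbc:label="',
             esc(g), '"', extra, '/>')
    }
    lines <- c(lines, '    <fbc:listOfGeneProducts>',
               vapply(all_genes, gene_line, character(1)),
               '    </fbc:listOfGeneProducts>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
}
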