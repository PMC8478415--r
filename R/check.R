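# Pedigree validation, harmonization and repair.
#
# check_pedigree() applies, in order: structural checks (unique IDs, parent
# references, proband present, no one their own ancestor), value-range
# checks, sex-cancer compatibility, germline-column resolution to default
# variants, heredity harmonization of race and ancestry, identical-twin
# consistency, loop detection, disconnected-member removal and pseudo-parent
# insertion. Every automatic change is reported in the returned
# check_report; unresolvable inconsistencies raise classed errors.

new_check_report <- function() {
  structure(list(messages = character(0), warnings = character(0),
                 changed_ids = list()),
            class = "check_report")
}

report_msg <- function(report, msg) {
  report$messages <- c(report$messages, msg)
  report
}

report_warn <- function(report, msg) {
  report$warnings <- c(report$warnings, msg)
  warning(msg, call. = FALSE)
  report
}

report_change <- function(report, kind, ids) {
  report$changed_ids[[kind]] <- sort(unique(c(report$changed_ids[[kind]],
                                              as.integer(ids))))
  report
}

#' @export
print.check_report <- function(x, ...) {
  cat("<check_report>\n")
  for (m in x$messages) cat("  ", m, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  if (!length(x$messages) && !length(x$warnings)) cat("  (no findings)\n")
  invisible(x)
}

# ---- loop detection ---------------------------------------------------

# Marriage-node graph: one node per individual plus one node per mating
# unit (a parent pair appearing in some child's record), with edges
# parent -- mating -- child. A pedigree contains a loop iff this undirected
# graph has a cycle. A single recorded parent is keyed together with an
# "unknown co-parent" placeholder so that shared single-parent sibships map
# to one mating unit (which is also how pseudo-parent insertion resolves
# them).

marriage_graph <- function(ped) {
  edges <- character(0)
  key <- function(m, f) {
    m <- if (is.na(m)) "" else as.character(m)
    f <- if (is.na(f)) "" else as.character(f)
    paste0("m:", m, "|", f)
  }
  for (i in seq_len(nrow(ped))) {
    m <- ped$MotherID[i]; f <- ped$FatherID[i]
    if (is.na(m) && is.na(f)) next
    mk <- key(m, f)
    if (!is.na(m)) edges <- c(edges, paste0("i:", m), mk)
    if (!is.na(f)) edges <- c(edges, paste0("i:", f), mk)
    edges <- c(edges, mk, paste0("i:", ped$ID[i]))
  }
  if (!length(edges)) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  igraph::simplify(igraph::graph_from_edgelist(matrix(edges, ncol = 2,
                                                      byrow = TRUE),
                                               directed = FALSE))
}

#' Detect pedigree loops
#'
#' A loop is a cycle in the marriage-node graph (individuals plus mating
#' units), e.g. intermarried sibling pairs or cousin matings. Looped
#' pedigrees are rejected by the engine.
#'
#' @param ped A pedigree tibble.
#' @return A list of loop descriptions (possibly empty); each element is the
#'   integer vector of individual IDs lying on one cycle.
#' @export
detect_loops <- function(ped) {
  g <- marriage_graph(ped)
  loops <- list()
  repeat {
    if (igraph::ecount(g) <= igraph::vcount(g) - igraph::count_components(g)) {
      break  # forest: no cycles left
    }
    gr <- igraph::girth(g)
    cyc <- igraph::as_ids(gr$circle)
    ids <- as.integer(sub("^i:", "", cyc[startsWith(cyc, "i:")]))
    loops[[length(loops) + 1L]] <- sort(ids)
    g <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, c(cyc[1L], cyc[2L])))
  }
  loops
}

# ---- connectivity -----------------------------------------------------

#' Remove family members disconnected from every proband
#'
#' Connectivity is taken through parent-child edges: members linked to a
#' proband only by a mating with no shared children in the pedigree carry no
#' information about the proband's genotype and are removed together with
#' their side of the family. The proband's posterior is unchanged by the
#' removal.
#'
#' @param ped A pedigree tibble with at least one proband.
#' @return A list with elements `pedigree` (the retained rows) and
#'   `removed_ids` (integer vector).
#' @export
remove_disconnected <- function(ped) {
  if (!any(ped$isProband == 1L)) {
    mr_error("pedigree has no proband", "mendelrisk_validation_error")
  }
  ids <- as.character(ped$ID)
  g <- igraph::add_vertices(igraph::make_empty_graph(directed = FALSE),
                            length(ids), name = ids)
  edges <- character(0)
  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$MotherID[i], ped$FatherID[i])) {
      if (!is.na(p)) edges <- c(edges, as.character(p), ids[i])
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership[ids]
  keep_comps <- unique(comp[ped$isProband == 1L])
  keep <- comp %in% keep_comps
  removed <- ped$ID[!keep]
  out <- ped[keep, , drop = FALSE]
  if (any(ped$isProband == 1L & !ped$ID %in% out$ID)) {
    # cannot happen: probands define the kept components
    stop("internal error: proband removed")
  }
  list(pedigree = out, removed_ids = as.integer(removed))
}

# ---- pseudo-parents ---------------------------------------------------

#' Insert pseudo-parents for single-parent individuals
#'
#' Peeling links non-founders through both parents. When only one parent is
#' recorded, a synthetic founder of the opposite sex is added: no phenotype,
#' unknown current age, ancestry and race copied from the known parent so
#' that its founder prior matches the known parent's population. All
#' children sharing the same single recorded parent share one pseudo-parent.
#'
#' @param ped A pedigree tibble.
#' @return A list with elements `pedigree` and `added_ids`.
#' @export
add_pseudo_parents <- function(ped) {
  added <- integer(0)
  next_id <- max(ped$ID) + 1L
  # group children by (known parent, missing side)
  need <- which(xor(is.na(ped$MotherID), is.na(ped$FatherID)))
  if (!length(need)) return(list(pedigree = ped, added_ids = added))
  groups <- split(need, paste0(
    ifelse(is.na(ped$MotherID[need]), "M", "F"), ":",
    ifelse(is.na(ped$MotherID[need]), ped$FatherID[need], ped$MotherID[need])))
  for (grp in groups) {
    missing_mother <- is.na(ped$MotherID[grp[1L]])
    known_id <- if (missing_mother) ped$FatherID[grp[1L]] else ped$MotherID[grp[1L]]
    known <- ped_row(ped, known_id)
    new_row <- ped[1, , drop = FALSE]
    for (col in names(new_row)) new_row[[col]] <- new_row[[col]][NA]
    new_row$ID <- next_id
    new_row$Sex <- if (missing_mother) 0L else 1L
    new_row$MotherID <- NA_integer_
    new_row$FatherID <- NA_integer_
    new_row$isProband <- 0L
    new_row$CurAge <- NA_integer_
    new_row$isDead <- NA_integer_
    new_row$Twins <- 0L
    new_row$race <- if (nrow(known)) known$race else NA_character_
    new_row$Ancestry <- if (nrow(known)) known$Ancestry else NA_character_
    for (tag in pedigree_cancers(ped)) {
      new_row[[aff_col(tag)]] <- 0L
      new_row[[age_col(tag)]] <- NA_integer_
    }
    if ("riskmod" %in% names(ped)) new_row$riskmod <- list(character(0))
    if ("InterAge" %in% names(ped)) new_row$InterAge <- list(integer(0))
    if (missing_mother) {
      ped$MotherID[grp] <- next_id
    } else {
      ped$FatherID[grp] <- next_id
    }
    ped <- bind_rows(ped, new_row)
    added <- c(added, next_id)
    next_id <- next_id + 1L
  }
  list(pedigree = ped, added_ids = added)
}

# ---- main check -------------------------------------------------------

#' Validate, harmonize and repair a pedigree
#'
#' Runs the full preprocessing pipeline and returns a pedigree that the
#' inference engines accept, together with a report of every message,
#' warning and automatic change. Unresolvable inconsistencies (a diagnosis
#' incompatible with the individual's sex, a pedigree loop, no proband,
#' inconsistent identical twins) raise classed errors.
#'
#' @param ped A pedigree tibble (see [read_pedigree()]).
#' @param db A `parameter_database` or a prebuilt `model_database`.
#' @param cancers,genes Passed to [build_model_database()] when `db` is a
#'   `parameter_database`.
#' @return A list with elements `pedigree` (repaired) and `report` (a
#'   `check_report`).
#' @export
check_pedigree <- function(ped, db, cancers = NULL, genes = NULL) {
  ped <- as_pedigree(ped)
  mdb <- if (inherits(db, "model_database")) {
    db
  } else {
    build_model_database(db, cancers = cancers, genes = genes, pedigree = ped)
  }
  report <- new_check_report()
  report <- report_msg(report, sprintf(
    "Model has %d cancer(s) - %s - and %d gene(s) - %s",
    length(mdb$cancers), paste(mdb$cancers, collapse = ", "),
    length(mdb$gene_variants), paste(mdb$gene_variants, collapse = ", ")))

  # structural
  if (!any(ped$isProband == 1L, na.rm = TRUE)) {
    mr_error("pedigree has no proband (isProband is never 1)",
             "mendelrisk_validation_error")
  }
  for (side in c("MotherID", "FatherID")) {
    refs <- ped[[side]]
    missing_ref <- !is.na(refs) & !refs %in% ped$ID
    if (any(missing_ref)) {
      mr_error(paste0(side, " of individual(s) ",
                      paste(ped$ID[missing_ref], collapse = ", "),
                      " is not in the pedigree"),
               "mendelrisk_validation_error")
    }
    parent_sex <- ped$Sex[match(refs, ped$ID)]
    want <- if (side == "MotherID") 0L else 1L
    bad_sex <- !is.na(refs) & !is.na(parent_sex) & parent_sex != want
    if (any(bad_sex)) {
      mr_error(paste0(side, " of individual(s) ",
                      paste(ped$ID[bad_sex], collapse = ", "),
                      " does not have the required sex"),
               "mendelrisk_validation_error")
    }
  }
  if (anyNA(ped$Sex) || !all(ped$Sex %in% c(0L, 1L))) {
    mr_error("Sex must be 0 (female) or 1 (male) for every individual",
             "mendelrisk_validation_error")
  }
  assert_acyclic_parentage(ped)

  # value ranges
  tags <- pedigree_cancers(ped)
  over_age <- which(!is.na(ped$CurAge) & ped$CurAge > MAX_AGE)
  if (length(over_age)) {
    ped$CurAge[over_age] <- MAX_AGE
    report <- report_warn(report, paste0(
      "ID ", paste(ped$ID[over_age], collapse = ","),
      " 's CurAge exceeds ", MAX_AGE, " and has been clamped to ", MAX_AGE))
    report <- report_change(report, "age_clamped", ped$ID[over_age])
  }
  if (any(!is.na(ped$CurAge) & ped$CurAge < 1L)) {
    mr_error("CurAge must be a strictly positive integer",
             "mendelrisk_validation_error")
  }
  for (tag in tags) {
    aff <- ped[[aff_col(tag)]]
    age <- ped[[age_col(tag)]]
    if (any(!is.na(aff) & !aff %in% c(0L, 1L))) {
      mr_error(paste0(aff_col(tag), " must be 0 or 1"),
               "mendelrisk_validation_error")
    }
    over <- which(!is.na(age) & age > MAX_AGE)
    if (length(over)) {
      ped[[age_col(tag)]][over] <- MAX_AGE
      age <- ped[[age_col(tag)]]
      report <- report_warn(report, paste0(
        "ID ", paste(ped$ID[over], collapse = ","), " 's ", age_col(tag),
        " exceeds ", MAX_AGE, " and has been clamped to ", MAX_AGE))
      report <- report_change(report, "age_clamped", ped$ID[over])
    }
    if (any(!is.na(age) & age < 1L)) {
      mr_error(paste0(age_col(tag), " must be a strictly positive integer"),
               "mendelrisk_validation_error")
    }
    bad <- which(!is.na(age) & !is.na(ped$CurAge) & age > ped$CurAge)
    if (length(bad)) {
      mr_error(paste0("ID ", paste(ped$ID[bad], collapse = ","), " 's ",
                      age_col(tag), " exceeds their censoring age CurAge"),
               "mendelrisk_validation_error")
    }
    spurious <- which(!is.na(age) & (is.na(aff) | aff == 0L))
    if (length(spurious)) {
      ped[[age_col(tag)]][spurious] <- NA_integer_
      report <- report_warn(report, paste0(
        "ID ", paste(ped$ID[spurious], collapse = ","), " 's ", age_col(tag),
        " has been dropped because ", aff_col(tag), " is not 1"))
      report <- report_change(report, "diag_age_dropped", ped$ID[spurious])
    }
  }

  # sex-cancer compatibility, derived from the penetrance support
  for (tag in intersect(tags, names(mdb$cancer_tags))) {
    cancer <- unname(mdb$cancer_tags[tag])
    for (sex in c(0L, 1L)) {
      slice <- mdb$penetrance[cancer, , , SEXES[sex + 1L], , , drop = FALSE]
      if (any(slice > 0)) next
      affected <- which(!is.na(ped[[aff_col(tag)]]) &
                          ped[[aff_col(tag)]] == 1L & ped$Sex == sex)
      if (length(affected)) {
        mr_error(paste0("ID ", paste(ped$ID[affected], collapse = ","),
                        " has a ", cancer, " diagnosis incompatible with their sex"),
                 "mendelrisk_validation_error")
      }
    }
  }

  # germline columns resolve to the default variant labels
  for (g in mdb$genes) {
    if (g %in% names(ped) && any(!is.na(ped[[g]]))) {
      report <- report_msg(report, paste0(
        "Germline testing results for ", g,
        " are assumed to be for default variant ", mdb$gene_variant_map[[g]], "."))
    }
  }

  # heredity harmonization, top-down so resets propagate to descendants
  harmonized <- harmonize_heredity(ped, report)
  ped <- harmonized$pedigree
  report <- harmonized$report

  # identical-twin consistency
  for (g in setdiff(unique(ped$Twins[ped$Twins > 0L]), 0L)) {
    rows <- which(ped$Twins == g)
    if (length(rows) < 2L) next
    same <- function(x) length(unique(x[rows])) == 1L
    if (!same(ped$MotherID) || !same(ped$FatherID)) {
      mr_error(paste0("identical twin set ", g, " (ID ",
                      paste(ped$ID[rows], collapse = ","),
                      ") does not share both parents"),
               "mendelrisk_validation_error")
    }
    if (!same(ped$Sex) || !same(ped$race) || !same(ped$Ancestry)) {
      mr_error(paste0("identical twin set ", g, " (ID ",
                      paste(ped$ID[rows], collapse = ","),
                      ") must share sex, race and ancestry"),
               "mendelrisk_validation_error")
    }
  }

  # loops
  loops <- detect_loops(ped)
  if (length(loops)) {
    mr_error(paste0("pedigree contains ", length(loops), " loop(s); ",
                    "e.g. through individual(s) ",
                    paste(loops[[1]], collapse = ", "),
                    ". Looped pedigrees are not supported."),
             "mendelrisk_loop_error")
  }

  # disconnected members
  rd <- remove_disconnected(ped)
  if (length(rd$removed_ids)) {
    report <- report_msg(report, paste0(
      "ID ", paste(rd$removed_ids, collapse = ","),
      " are disconnected from every proband and have been removed"))
    report <- report_change(report, "removed_disconnected", rd$removed_ids)
    ped <- rd$pedigree
  }
  if (nrow(ped) == 1L) {
    report <- report_warn(report,
      "the proband has no connected relatives; results use population priors only")
  }

  # pseudo-parents
  pp <- add_pseudo_parents(ped)
  if (length(pp$added_ids)) {
    report <- report_msg(report, paste0(
      "pseudo-parent(s) ", paste(pp$added_ids, collapse = ","),
      " have been added for individuals with a single recorded parent"))
    report <- report_change(report, "pseudo_parent_added", pp$added_ids)
    ped <- pp$pedigree
  }

  list(pedigree = ped, report = report)
}

assert_acyclic_parentage <- function(ped) {
  edges <- character(0)
  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$MotherID[i], ped$FatherID[i])) {
      if (!is.na(p)) edges <- c(edges, as.character(p), as.character(ped$ID[i]))
    }
  }
  if (!length(edges)) return(invisible(TRUE))
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = TRUE)
  if (!igraph::is_dag(g)) {
    mr_error("pedigree parentage is cyclic: some individual is their own ancestor",
             "mendelrisk_validation_error")
  }
  invisible(TRUE)
}

# A child's race/ancestry must be consistent with its parents: equal to the
# parents' shared value when they agree, or to either parental value (or the
# neutral category) when they differ. Conflicts reset the child to the
# neutral category (All_Races / nonAJ) with a message; processing is
# top-down by generation so resets cascade to descendants.
harmonize_heredity <- function(ped, report) {
  depth <- generation_depth(ped)
  order_rows <- order(depth, ped$ID)
  for (spec in list(list(col = "Ancestry", neutral = "nonAJ", label = "Ancestry"),
                    list(col = "race", neutral = "All_Races", label = "race"))) {
    changed <- integer(0)
    for (i in order_rows) {
      m <- ped$MotherID[i]; f <- ped$FatherID[i]
      if (is.na(m) && is.na(f)) next
      vals <- c(if (!is.na(m)) ped[[spec$col]][match(m, ped$ID)],
                if (!is.na(f)) ped[[spec$col]][match(f, ped$ID)])
      vals <- unique(vals[!is.na(vals)])
      if (!length(vals)) next
      child <- ped[[spec$col]][i]
      if (is.na(child)) next
      ok <- child %in% c(vals, spec$neutral)
      if (!ok) {
        ped[[spec$col]][i] <- spec$neutral
        changed <- c(changed, ped$ID[i])
      }
    }
    if (length(changed)) {
      report <- report_msg(report, paste0(
        "ID ", paste(changed, collapse = ","), " 's ", spec$label,
        " has been changed to ", spec$neutral, " to meet heredity consistency"))
      report <- report_change(report,
                              paste0(tolower(spec$label), "_reset"), changed)
    }
  }
  list(pedigree = ped, report = report)
}

# Generation depth: founders 0, child = 1 + max(parent depths).
generation_depth <- function(ped) {
  n <- nrow(ped)
  depth <- rep(NA_integer_, n)
  mo <- match(ped$MotherID, ped$ID)
  fa <- match(ped$FatherID, ped$ID)
  repeat {
    progressed <- FALSE
    for (i in seq_len(n)) {
      if (!is.na(depth[i])) next
      parents <- c(mo[i], fa[i])
      parents <- parents[!is.na(parents)]
      if (!length(parents)) {
        depth[i] <- 0L
        progressed <- TRUE
      } else if (all(!is.na(depth[parents]))) {
        depth[i] <- 1L + max(depth[parents])
        progressed <- TRUE
      }
    }
    if (all(!is.na(depth))) break
    if (!progressed) {
      mr_error("pedigree parentage is cyclic: generation depth is undefined",
               "mendelrisk_validation_error")
    }
  }
  depth
}
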