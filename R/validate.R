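# Report-only consistency checking. Construction (newPGDB) already rejects
# duplicate and dangling frame IDs when check = TRUE; validatePGDB() re-checks
# those plus every structural invariant and returns all findings instead of
# stopping at the first.

violation <- function(severity, rule, frameId, message) {
  data.frame(severity = severity, rule = rule, frameId = frameId,
             message = message, stringsAsFactors = FALSE)
}

emptyReport <- function() {
  data.frame(severity = character(0), rule = character(0),
             frameId = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a PGDB's internal consistency
#'
#' Checks referential integrity, stoichiometric coefficients, pathway
#' non-emptiness, gene-product kinds, and compartment plausibility for
#' transporters. Never throws: all findings are returned as a report.
#'
#' @param pgdb a [PGDB-class] (possibly constructed with `check = FALSE`).
#' @return a data.frame with columns severity ("error"/"warning"), rule,
#'   frameId, message; zero rows iff the PGDB is internally consistent
#'   (warnings count as findings but not as inconsistency — see
#'   [isCleanReport()]).
#' @export
validatePGDB <- function(pgdb) {
  ents <- pgdb@entities
  ids <- names(ents)
  rep <- list(emptyReport())
  add <- function(...) rep[[length(rep) + 1L]] <<- violation(...)

  kindOf <- function(id) if (id %in% ids) ents[[id]]$kind else NA_character_

  for (e in ents) {
    fid <- e$frameId
    if (!nzchar(e$name %||% ""))
      add("error", "empty_name", fid, "entity has an empty name")
    dang <- setdiff(entityRefs(e), ids)
    if (length(dang))
      add("error", "dangling_reference", fid,
          paste("unresolved frame IDs:", paste(sort(dang), collapse = ", ")))
    if (e$kind == "reaction") {
      coefs <- c(e$substrates, e$products)
      if (length(coefs) && any(coefs <= 0))
        add("error", "nonpositive_coefficient", fid,
            "stoichiometric coefficients must be > 0")
      for (cid in intersect(c(names(e$substrates), names(e$products)), ids))
        if (kindOf(cid) != "compound")
          add("error", "bad_reference_kind", fid,
              paste0("'", cid, "' is not a compound"))
      for (pid in intersect(e$enzymes, ids))
        if (kindOf(pid) != "protein")
          add("error", "bad_reference_kind", fid,
              paste0("enzyme '", pid, "' is not a protein"))
    }
    if (e$kind == "pathway" && length(e$reactions) == 0)
      add("error", "empty_pathway", fid, "pathway has no reactions")
    if (e$kind == "gene") {
      for (pid in intersect(e$products, ids))
        if (!kindOf(pid) %in% c("protein", "rna"))
          add("error", "bad_reference_kind", fid,
              paste0("gene product '", pid, "' is not a protein or RNA"))
    }
    if (e$kind == "protein" && isTRUE(e$isTransporter)) {
      # a transporter should act in a membrane: all-cytosolic catalysis is suspect
      rxns <- Filter(function(r) r$kind == "reaction" && fid %in% r$enzymes, ents)
      if (length(rxns) &&
          all(vapply(rxns, function(r) r$compartment, "") == "cytosol"))
        add("warning", "transporter_in_cytosol", fid,
            "transporter's reactions are all cytosolic; expected a membrane compartment")
    }
  }
  do.call(rbind, rep)
}

#' @rdname validatePGDB
#' @param report a report from [validatePGDB()].
#' @param allowWarnings if `TRUE`, only "error" rows count.
#' @export
isCleanReport <- function(report, allowWarnings = FALSE) {
  if (allowWarnings) !any(report$severity == "error") else nrow(report) == 0L
}
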