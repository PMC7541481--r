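#' Reference map of functional positions
#'
#' Records where the ion-transport machinery sits on a reference sequence:
#' the helix-C triplet (proton acceptor, its hydrogen-bond partner, proton
#' donor), the Schiff-base counterion, the extracellular proton-release pair,
#' and the retinal-binding Schiff-base lysine. In bacteriorhodopsin-mature
#' numbering these are Asp85/Thr89/Asp96, Asp212, Glu194/Glu204 and Lys216;
#' in the N2098R pump, Asp74/Thr78/Glu85, Asp200, Glu182/Glu192 and Lys204.
#'
#' @param reference_id id of the reference sequence the map belongs to.
#' @param positions named integer vector over the seven roles (same names as
#'   in [scaffold_spec()]), distinct, within the reference length.
#' @param reference_length length of the reference (for validation).
#' @param numbering_label free-text label of the numbering convention, e.g.
#'   `"BR-mature"` or `"scaffold"`; never inferred.
#' @return An object of class `reference_map`.
#' @export
reference_map <- function(reference_id, positions, reference_length,
                          numbering_label = "scaffold") {
  if (!setequal(names(positions), ROLES))
    stop("positions must name exactly the roles: ", paste(ROLES, collapse = ", "))
  positions <- vapply(positions[ROLES], as.integer, integer(1))
  if (anyDuplicated(positions)) stop("reference positions must be distinct")
  if (any(positions < 1L | positions > reference_length))
    stop("reference positions must lie within the reference")
  structure(list(reference_id = reference_id, positions = positions,
                 numbering_label = numbering_label),
            class = "reference_map")
}

#' Extract the helix-C motif and accessory residues from a query
#'
#' Aligns the query to the mapped reference and reads off, for each
#' functional role, the query residue sitting in the reference-numbered
#' column, reporting its 1-based position in the unaligned query. Roles whose
#' reference column aligns to a gap (or falls outside the aligned region) are
#' reported as `"-"` with a warning, never an error.
#'
#' @param query query protein sequence.
#' @param reference reference protein sequence the map belongs to.
#' @param refmap a [reference_map()].
#' @param params an [alignment_params()].
#' @return A list of class `motif_call`: `motif_triplet` (3 letters, `-` for
#'   gap), `schiff_lysine_present`, `counterion_residue`, `release_pair`,
#'   `query_positions` (named, `NA` where gapped), `gaps` (roles aligned to a
#'   gap).
#' @export
extract_motif <- function(query, reference, refmap, params = alignment_params()) {
  stopifnot(inherits(refmap, "reference_map"))
  a <- align_pair(query, reference, params)
  qa <- strsplit(a$query_aln, "")[[1]]
  ra <- strsplit(a$ref_aln, "")[[1]]
  # walk the aligned columns, tracking unaligned coordinates
  qpos <- a$query_start - 1L
  rpos <- a$ref_start - 1L
  res <- setNames(rep("-", length(ROLES)), ROLES)
  pos <- setNames(rep(NA_integer_, length(ROLES)), ROLES)
  want <- refmap$positions
  for (i in seq_along(qa)) {
    if (qa[i] != "-") qpos <- qpos + 1L
    if (ra[i] != "-") {
      rpos <- rpos + 1L
      hitrole <- names(want)[want == rpos]
      if (length(hitrole) == 1L && qa[i] != "-") {
        res[hitrole] <- qa[i]
        pos[hitrole] <- qpos
      }
    }
  }
  gaps <- names(res)[res == "-"]
  if (length(gaps) > 0L)
    warning("roles aligned to a gap or outside the alignment: ",
            paste(gaps, collapse = ", "))
  structure(list(
    motif_triplet = paste(res[c("acceptor", "hbond_partner", "donor")], collapse = ""),
    schiff_lysine_present = identical(unname(res[["schiff_lysine"]]), "K"),
    counterion_residue = unname(res[["counterion"]]),
    release_pair = paste(res[c("release1", "release2")], collapse = ""),
    query_positions = pos, gaps = gaps
  ), class = "motif_call")
}

#' Default transport-function rule table
#'
#' Ordered first-match rules from motif call to transport function. The order
#' is explicit configuration: the lysine check comes first (no Schiff base,
#' no photochemistry), then the proton-pump motifs DTD/DTE -- the motifs of
#' bacteriorhodopsin-type and of the cyanorhodopsin clade, whose members were
#' shown in heterologous pH assays to pump protons outward -- before the
#' sodium (NDQ) and chloride (NTQ / TSD-type) pump motifs.
#'
#' @return A data.frame with columns `rule_id` and `label`, in firing order.
#' @export
function_rules <- function() {
  data.frame(
    rule_id = c("no_schiff_lysine", "dtd_dte_pump", "ndq_na_pump",
                "cl_pump_motif", "acceptor_no_donor", "fallback"),
    label = c("nonfunctional_opsin", "outward_H_pump", "Na_pump",
              "inward_Cl_pump", "inward_H_pump", "sensor_or_unknown"))
}

#' Predict transport function from a motif call
#'
#' Applies [function_rules()] in order; exactly one rule fires for any call,
#' so the prediction is total.
#'
#' @param call a `motif_call` from [extract_motif()].
#' @param rules rule table (firing order matters); defaults to
#'   [function_rules()].
#' @return A list of class `function_prediction`: `label`, `rule_id`,
#'   `evidence` (the motif-call fields the rule consumed).
#' @export
predict_function <- function(call, rules = function_rules()) {
  trip <- call$motif_triplet
  acc <- substr(trip, 1, 1); don <- substr(trip, 3, 3)
  acidic <- c("D", "E")
  fires <- function(rule_id) switch(rule_id,
    no_schiff_lysine  = !isTRUE(call$schiff_lysine_present),
    dtd_dte_pump      = trip %in% c("DTD", "DTE") && acc %in% acidic,
    ndq_na_pump       = trip == "NDQ",
    cl_pump_motif     = trip %in% c("NTQ", "TSA", "TSD"),
    acceptor_no_donor = acc %in% acidic && !(don %in% acidic),
    fallback          = TRUE,
    stop("unknown rule_id: ", rule_id))
  for (i in seq_len(nrow(rules))) {
    if (fires(rules$rule_id[i])) {
      return(structure(list(
        label = rules$label[i], rule_id = rules$rule_id[i],
        evidence = list(motif_triplet = trip,
                        schiff_lysine_present = call$schiff_lysine_present)),
        class = "function_prediction"))
    }
  }
  stop("rule table did not cover the call; include a fallback rule")
}
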