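# Download-free fixture bed.
#
# Reference SMILES are transcribed from the primary literature / public
# structure databases (the original reports depict the structures rather
# than print SMILES); the transcription for each entry is annotated with
# its expected functional-group content so the matcher can be audited
# against an independent reading of the published structure.

.reference_data <- function() {
  # name | smiles | biosynthetic type | expected searchable-group counts
  list(
    list("enterobactin",
         paste0("O=C1OCC(NC(=O)c2cccc(O)c2O)C(=O)OCC(NC(=O)c2cccc(O)c2O)",
                "C(=O)OCC1NC(=O)c1cccc(O)c1O"),
         "NRPS", c("catecholate" = 3, "phenolate" = 3)),
    list("bacillibactin",
         paste0("CC1OC(=O)C(NC(=O)CNC(=O)c2cccc(O)c2O)C(C)OC(=O)C(NC(=O)",
                "CNC(=O)c2cccc(O)c2O)C(C)OC(=O)C1NC(=O)CNC(=O)c2cccc(O)c2O"),
         "NRPS", c("catecholate" = 3, "phenolate" = 3)),
    list("vibriobactin",
         paste0("Oc1cccc(C(=O)N(CCCNC(=O)C2N=C(c3cccc(O)c3O)OC2C)CCCNC(=O)",
                "C2N=C(c3cccc(O)c3O)OC2C)c1O"),
         "NRPS", c("catecholate" = 3, "phenolate" = 1,
                   "hydroxyphenyloxazoline" = 2)),
    list("desferrioxamine B",
         paste0("NCCCCCN(O)C(=O)CCC(=O)NCCCCCN(O)C(=O)CCC(=O)NCCCCCN(O)",
                "C(C)=O"),
         "NIS", c("hydroxamate" = 3)),
    list("desferrioxamine E",
         paste0("O=C1CCC(=O)N(O)CCCCCNC(=O)CCC(=O)N(O)CCCCCNC(=O)CCC(=O)",
                "N(O)CCCCCN1"),
         "NIS", c("hydroxamate" = 3)),
    list("ferrichrome",
         paste0("O=C1NCC(=O)NCC(=O)NCC(=O)NC(CCCN(O)C(C)=O)C(=O)NC(CCCN(O)",
                "C(C)=O)C(=O)NC1CCCN(O)C(C)=O"),
         "NRPS", c("hydroxamate" = 3)),
    list("aerobactin",
         paste0("OC(=O)C(O)(CC(=O)NC(C(O)=O)CCCCN(O)C(C)=O)CC(=O)NC(C(O)=O)",
                "CCCCN(O)C(C)=O"),
         "NIS", c("hydroxamate" = 2, "carboxylate-in-citrate" = 2,
                  "alpha-hydroxycarboxylate-in-citrate" = 2)),
    list("schizokinen",
         "OC(=O)C(O)(CC(=O)NCCCN(O)C(C)=O)CC(=O)NCCCN(O)C(C)=O",
         "NIS", c("hydroxamate" = 2, "carboxylate-in-citrate" = 2,
                  "alpha-hydroxycarboxylate-in-citrate" = 2)),
    list("staphyloferrin A",
         paste0("OC(=O)CC(O)(C(O)=O)CC(=O)NCCCC(NC(=O)CC(O)(CC(O)=O)C(O)=O)",
                "C(O)=O"),
         "NIS", c("carboxylate-in-citrate" = 2,
                  "alpha-hydroxycarboxylate-in-citrate" = 2)),
    list("rhizoferrin",
         "OC(=O)CC(O)(C(O)=O)CC(=O)NCCCCNC(=O)CC(O)(CC(O)=O)C(O)=O",
         "NIS", c("carboxylate-in-citrate" = 2,
                  "alpha-hydroxycarboxylate-in-citrate" = 2)),
    list("yersiniabactin",
         "OC(=O)C1(C)CSC(=N1)C(O)C(C)(C)C1CSC(N1)C1CSC(=N1)c1ccccc1O",
         "PKS-hybrid", c("hydroxyphenylthiazoline" = 1)),
    list("pyochelin",
         "OC(=O)C1CSC(N1C)C1CSC(=N1)c1ccccc1O",
         "NRPS", c("hydroxyphenylthiazoline" = 1)),
    list("petrobactin",
         paste0("Oc1ccc(cc1O)C(=O)NCCCCNCCCNC(=O)CC(O)(C(O)=O)CC(=O)NCCCN",
                "CCCCNC(=O)c1ccc(O)c(O)c1"),
         "NIS", c("catecholate" = 2, "carboxylate-in-citrate" = 2,
                  "alpha-hydroxycarboxylate-in-citrate" = 2)),
    list("cepabactin", "COc1ccc(=O)n(O)c1C",
         "unknown", c("cyclic hydroxamate" = 1)),
    list("quinolobactin", "COc1cc(nc2c(O)cccc12)C(O)=O",
         "unknown", c("8-hydroxyquinoline" = 1)),
    list("graminine", "NC(CCCN(O)N=O)C(O)=O",
         "unknown", c("diazeniumdiolate" = 1, "alpha-aminocarboxylate" = 1))
  )
}

#' Curated reference siderophores
#'
#' At least ten literature-standard siderophore structures spanning the
#' major chelation chemistries: catecholate (enterobactin, bacillibactin,
#' vibriobactin, petrobactin), hydroxamate (desferrioxamines B and E,
#' ferrichrome, aerobactin, schizokinen), citrate carboxylate (aerobactin,
#' staphyloferrin A, rhizoferrin, petrobactin),
#' phenolate/oxazoline-thiazoline (yersiniabactin, pyochelin,
#' vibriobactin), plus exemplars of the rarer groups (cepabactin,
#' quinolobactin, graminine).
#'
#' @return A `mol_records` table tagged `knownset`, with an attribute
#'   `expected_counts` (named list of expected searchable-group counts per
#'   record, from independent inspection of the published structures).
#' @export
reference_set <- function() {
  d <- .reference_data()
  ids <- vapply(d, function(x) gsub(" ", "_", tolower(x[[1]])), character(1))
  recs <- mol_records(
    record_id = ids,
    smiles = vapply(d, `[[`, "", 2),
    name = vapply(d, `[[`, "", 1),
    biosynthetic_type = vapply(d, `[[`, "", 3),
    source_tag = "knownset")
  attr(recs, "expected_counts") <- setNames(lapply(d, `[[`, 4), ids)
  recs
}

#' Natural-product-like decoys without any searchable group
#'
#' Sugars, terpenes, alkaloids, simple phenolics and acids: molecules a
#' natural-product library is full of, none carrying an intact
#' iron-coordinating group from the registry.  Some (vanillin, ferulic
#' acid) deliberately carry a *blocked* (O-methylated) catechol so the veto
#' path is exercised by realistic negatives.
#'
#' @return A `mol_records` table tagged `background`.
#' @export
decoy_set <- function() {
  d <- c(
    glucose = "OCC1OC(O)C(O)C(O)C1O",
    sucrose = "OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O",
    sorbitol = "OCC(O)C(O)C(O)C(O)CO",
    salicin = "OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O",
    citric_acid = "OC(=O)CC(O)(CC(O)=O)C(O)=O",
    malic_acid = "OC(=O)CC(O)C(O)=O",
    stearic_acid = "CCCCCCCCCCCCCCCCCC(O)=O",
    limonene = "CC(=C)C1CCC(C)=CC1",
    menthol = "CC(C)C1CCC(C)CC1O",
    camphor = "CC1(C)C2CCC1(C)C(=O)C2",
    geraniol = "CC(C)=CCCC(C)=CCO",
    artemisinin = "CC1CCC2C(C)C(=O)OC3OC4(C)CCC1C23OO4",
    cholesterol = "CC(C)CCCC(C)C1CCC2C3CC=C4CC(O)CCC4(C)C3CCC12C",
    caffeine = "Cn1cnc2n(C)c(=O)n(C)c(=O)c12",
    nicotine = "CN1CCCC1c1cccnc1",
    indole = "c1ccc2[nH]ccc2c1",
    vanillin = "COc1cc(C=O)ccc1O",
    ferulic_acid = "COc1cc(C=CC(O)=O)ccc1O",
    resveratrol = "Oc1ccc(C=Cc2cc(O)cc(O)c2)cc1",
    umbelliferone = "Oc1ccc2C=CC(=O)Oc2c1")
  mol_records(record_id = names(d), smiles = unname(d),
              name = gsub("_", " ", names(d)), source_tag = "background")
}

#' Veto constructs: positives with chemically disabled groups
#'
#' Reference siderophores whose chelating oxygens have been O-alkylated so
#' that the parent group can no longer coordinate iron.  Each construct
#' must be vetoed by the screen while remaining highly similar
#' (Tanimoto > 0.60) to its parent.
#'
#' @return A `mol_records` table tagged `query` with a `parent_id` column.
#' @export
veto_constructs <- function() {
  d <- list(
    # all three hydroxamate N-OH oxygens methylated
    list("desferrioxamine B O-trimethyl", "desferrioxamine_b",
         paste0("NCCCCCN(OC)C(=O)CCC(=O)NCCCCCN(OC)C(=O)CCC(=O)NCCCCCN(OC)",
                "C(C)=O")),
    # one catechol hydroxyl methylated on each arm
    list("enterobactin O-trimethyl", "enterobactin",
         paste0("O=C1OCC(NC(=O)c2cccc(OC)c2O)C(=O)OCC(NC(=O)c2cccc(OC)c2O)",
                "C(=O)OCC1NC(=O)c1cccc(OC)c1O")),
    # hydroxamates blocked while the citrate core stays intact: exercises
    # the global veto on a molecule that still has searchable groups
    list("schizokinen O-dimethyl", "schizokinen",
         "OC(=O)C(O)(CC(=O)NCCCN(OC)C(C)=O)CC(=O)NCCCN(OC)C(C)=O"),
    # phenol of the hydroxyphenyl-thiazoline arm methylated
    list("pyochelin O-methyl", "pyochelin",
         "COc1ccccc1C1=NC(CS1)C1N(C)C(CS1)C(O)=O")
  )
  recs <- mol_records(
    record_id = vapply(d, function(x)
      paste0("veto_", gsub("[ -]", "_", tolower(x[[1]]))), character(1)),
    smiles = vapply(d, `[[`, "", 3),
    name = vapply(d, `[[`, "", 1),
    source_tag = "query")
  recs$parent_id <- vapply(d, `[[`, "", 2)
  recs
}

#' Fixture library specification
#'
#' @param n_positives,n_decoys,n_veto_constructs How many molecules to draw
#'   from [reference_set()], [decoy_set()], [veto_constructs()].
#' @param seed Integer seed; the same spec yields a byte-identical library.
#' @param positive_ids Optional record ids to force into the positive draw.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_positives, n_decoys, n_veto_constructs, seed,
                         positive_ids = NULL) {
  stopifnot(n_positives >= 0, n_decoys >= 0, n_veto_constructs >= 0)
  structure(list(n_positives = n_positives, n_decoys = n_decoys,
                 n_veto_constructs = n_veto_constructs, seed = seed,
                 positive_ids = positive_ids), class = "fixture_spec")
}

#' Generate a seeded synthetic screening library
#'
#' Draws the requested numbers of reference positives, decoys, and veto
#' constructs, shuffles them deterministically under the spec's seed, and
#' (optionally) writes the result in the library CSV format.  By
#' construction, screening the library recovers exactly the planted
#' positives.
#'
#' @param spec A [fixture_spec()].
#' @param path Optional output file; written via [write_library()].
#' @return The `mol_records` table (invisibly if `path` is given).
#' @export
make_library <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  refs <- reference_set()
  attr(refs, "expected_counts") <- NULL
  decs <- decoy_set()
  vets <- veto_constructs()
  vets$parent_id <- NULL
  if (spec$n_positives > nrow(refs) || spec$n_decoys > nrow(decs) ||
      spec$n_veto_constructs > nrow(vets)) {
    stop("fixture spec requests more molecules than the fixture sets hold")
  }
  lib <- with_seed(spec$seed, {
    pos_ids <- spec$positive_ids %||% character(0)
    pos_pool <- setdiff(refs$record_id, pos_ids)
    pos <- c(pos_ids,
             sample(pos_pool, spec$n_positives - length(pos_ids)))
    parts <- rbind(
      refs[match(pos, refs$record_id), , drop = FALSE],
      decs[sort(sample(nrow(decs), spec$n_decoys)), , drop = FALSE],
      vets[sort(sample(nrow(vets), spec$n_veto_constructs)), , drop = FALSE])
    parts[sample(nrow(parts)), , drop = FALSE]
  })
  rownames(lib) <- NULL
  class(lib) <- c("mol_records", "data.frame")
  if (!is.null(path)) {
    write_library(lib, path,
                  header = c(n_positives = spec$n_positives,
                             n_decoys = spec$n_decoys,
                             n_veto_constructs = spec$n_veto_constructs,
                             seed = spec$seed))
    return(invisible(lib))
  }
  lib
}
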