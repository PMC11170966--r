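# The functional-group pattern registry.
#
# Siderophores chelate Fe(III) through a small set of bidentate
# oxygen-donor moieties.  The registry holds three categories:
#   searchable      -- 15 iron-coordinating groups; any one of them makes a
#                      molecule a candidate
#   common_excluded -- groups counted for statistics but too ubiquitous in
#                      non-siderophores to trigger candidacy
#                      (alpha-hydroxycarboxylate, plain carboxylate)
#   modified_veto   -- 8 chemically blocked variants (O-alkylated or
#                      O-acylated chelating oxygens) that cannot form
#                      coordination bonds; their presence vetoes a molecule
#
# Every entry stores both a SMARTS string (used for the OpenBabel
# cross-check engine and the TSV dump) and an equivalent hand-built pattern
# graph consumed by the package's own matcher, which reports matched atom
# sets.  The exemplar comment names a depicted reference structure so the
# transcription can be audited.

ring6 <- function(s) {
  # aromatic six-ring bond block for atoms s..s+5
  p_bonds(s, s + 1, ":", s + 1, s + 2, ":", s + 2, s + 3, ":",
          s + 3, s + 4, ":", s + 4, s + 5, ":", s + 5, s, ":")
}

c_ar <- function() p_atom("C", arom = TRUE, ring = TRUE)
o_hydroxyl <- function() p_atom("O", arom = FALSE, heavy = 1, hmin = 1, hmax = 1)
o_carbonyl <- function() p_atom("O", arom = FALSE, heavy = 1, hmax = 0)
o_ether <- function() p_atom("O", arom = FALSE, heavy = 2, hmax = 0)

pattern_entry <- function(group_name, category, rarity, smarts, exemplar,
                          graph = NULL) {
  list(group_name = group_name, category = category, rarity = rarity,
       smarts = smarts, exemplar = exemplar, graph = graph)
}

default_pattern_list <- function() {
  list(
    ## -- searchable -------------------------------------------------------
    # exemplar: desferrioxamine B; acyclic N-hydroxy amide with free OH
    pattern_entry(
      "hydroxamate", "searchable", "common",
      "[CX3](=[OX1])[NX3][OX2H1]", "desferrioxamine B",
      pattern_graph(
        list(p_atom("C", arom = FALSE, xtot = 3), o_carbonyl(),
             p_atom("N", arom = FALSE, xtot = 3), o_hydroxyl()),
        p_bonds(1, 2, "=", 1, 3, "-", 3, 4, "-"))),
    # exemplar: cepabactin; 1-hydroxy-2-azinone (cyclic hydroxamate), ring
    # aromaticity left open because perception differs across toolkits
    pattern_entry(
      "cyclic hydroxamate", "searchable", "rare",
      "[OX2H1][#7X3]1[#6X3](=[OX1])[#6]~[#6]~[#6]~[#6]1", "cepabactin",
      pattern_graph(
        list(o_hydroxyl(), p_atom("N", xtot = 3, ring = TRUE),
             p_atom("C", xtot = 3, ring = TRUE), o_carbonyl(),
             p_atom("C", ring = TRUE), p_atom("C", ring = TRUE),
             p_atom("C", ring = TRUE), p_atom("C", ring = TRUE)),
        p_bonds(1, 2, "-", 2, 3, "~", 3, 4, "=", 3, 5, "~", 5, 6, "~",
                6, 7, "~", 7, 8, "~", 8, 2, "~"))),
    # exemplar: enterobactin (2,3-dihydroxybenzoyl arms); free ortho-diphenol
    pattern_entry(
      "catecholate", "searchable", "common",
      "[OX2H1]c1ccccc1[OX2H1]", "enterobactin",
      pattern_graph(
        c(replicate(6, c_ar(), simplify = FALSE),
          list(o_hydroxyl(), o_hydroxyl())),
        rbind(ring6(1), p_bonds(1, 7, "-", 2, 8, "-")))),
    # exemplar: salicyl amides; 2-hydroxyphenyl carbonyl
    pattern_entry(
      "phenolate", "searchable", "common",
      "[OX2H1]c1ccccc1[CX3]=[OX1]", "salicylate arm of mycobactin-type cores",
      pattern_graph(
        c(replicate(6, c_ar(), simplify = FALSE),
          list(o_hydroxyl(), p_atom("C", arom = FALSE, xtot = 3),
               o_carbonyl())),
        rbind(ring6(1), p_bonds(1, 7, "-", 2, 8, "-", 8, 9, "=")))),
    # exemplar: vibriobactin; 2-(2-hydroxyphenyl)-4,5-dihydrooxazole
    pattern_entry(
      "hydroxyphenyloxazoline", "searchable", "rare",
      "[OX2H1]c1ccccc1C2=NCCO2", "vibriobactin",
      pattern_graph(
        c(replicate(6, c_ar(), simplify = FALSE),
          list(o_hydroxyl(), p_atom("C", arom = FALSE, xtot = 3),
               p_atom("N", arom = FALSE, xtot = 2),
               p_atom("C", arom = FALSE), p_atom("C", arom = FALSE),
               o_ether())),
        rbind(ring6(1),
              p_bonds(1, 7, "-", 2, 8, "-", 8, 9, "=", 9, 10, "-",
                      10, 11, "-", 11, 12, "-", 12, 8, "-")))),
    # exemplar: yersiniabactin, pyochelin; 2-(2-hydroxyphenyl)thiazoline
    pattern_entry(
      "hydroxyphenylthiazoline", "searchable", "rare",
      "[OX2H1]c1ccccc1C2=NCCS2", "yersiniabactin",
      pattern_graph(
        c(replicate(6, c_ar(), simplify = FALSE),
          list(o_hydroxyl(), p_atom("C", arom = FALSE, xtot = 3),
               p_atom("N", arom = FALSE, xtot = 2),
               p_atom("C", arom = FALSE), p_atom("C", arom = FALSE),
               p_atom("S", arom = FALSE, heavy = 2, hmax = 0))),
        rbind(ring6(1),
              p_bonds(1, 7, "-", 2, 8, "-", 8, 9, "=", 9, 10, "-",
                      10, 11, "-", 11, 12, "-", 12, 8, "-")))),
    # exemplar: aromatized oxazole analogues of the azoline arms
    pattern_entry(
      "hydroxyphenyloxazole", "searchable", "rare",
      "[OX2H1]c1ccccc1-c2ncco2", "2-(2-hydroxyphenyl)oxazole",
      pattern_graph(
        c(replicate(6, c_ar(), simplify = FALSE),
          list(o_hydroxyl(), p_atom("C", arom = TRUE, ring = TRUE),
               p_atom("N", arom = TRUE, ring = TRUE),
               p_atom("C", arom = TRUE, ring = TRUE),
               p_atom("C", arom = TRUE, ring = TRUE),
               p_atom("O", arom = TRUE, ring = TRUE))),
        rbind(ring6(1),
              p_bonds(1, 7, "-", 2, 8, "-", 8, 9, ":", 9, 10, ":",
                      10, 11, ":", 11, 12, ":", 12, 8, ":")))),
    pattern_entry(
      "hydroxyphenylthiazole", "searchable", "rare",
      "[OX2H1]c1ccccc1-c2nccs2", "2-(2-hydroxyphenyl)thiazole",
      pattern_graph(
        c(replicate(6, c_ar(), simplify = FALSE),
          list(o_hydroxyl(), p_atom("C", arom = TRUE, ring = TRUE),
               p_atom("N", arom = TRUE, ring = TRUE),
               p_atom("C", arom = TRUE, ring = TRUE),
               p_atom("C", arom = TRUE, ring = TRUE),
               p_atom("S", arom = TRUE, ring = TRUE))),
        rbind(ring6(1),
              p_bonds(1, 7, "-", 2, 8, "-", 8, 9, ":", 9, 10, ":",
                      10, 11, ":", 11, 12, ":", 12, 8, ":")))),
    # exemplar: graminine, staphyloferrin backbones; free (non-amide) amine
    # alpha to a free carboxylic acid
    pattern_entry(
      "alpha-aminocarboxylate", "searchable", "common",
      "[NX3;H1,H2;!$([NX3][CX3]=[OX1])][CX4][CX3](=[OX1])[OX2H1]",
      "amino-acid terminus of graminine",
      pattern_graph(
        list(p_atom("N", arom = FALSE, hmin = 1, hmax = 2, xtot = 3,
                    not_acyl = TRUE),
             p_atom("C", arom = FALSE, xtot = 4),
             p_atom("C", arom = FALSE, xtot = 3), o_carbonyl(),
             o_hydroxyl()),
        p_bonds(1, 2, "-", 2, 3, "-", 3, 4, "=", 3, 5, "-"))),
    # exemplar: imidazole-carbinol chelator arm
    pattern_entry(
      "alpha-hydroxyimidazole", "searchable", "rare",
      "[OX2H1][CX4]c1nccn1", "2-(1-hydroxyalkyl)imidazole arm",
      pattern_graph(
        list(o_hydroxyl(), p_atom("C", arom = FALSE, xtot = 4),
             p_atom("C", arom = TRUE, ring = TRUE),
             p_atom("N", arom = TRUE, ring = TRUE),
             p_atom("C", arom = TRUE, ring = TRUE),
             p_atom("C", arom = TRUE, ring = TRUE),
             p_atom("N", arom = TRUE, ring = TRUE)),
        p_bonds(1, 2, "-", 2, 3, "-", 3, 4, ":", 4, 5, ":", 5, 6, ":",
                6, 7, ":", 7, 3, ":"))),
    # exemplar: graminine; N-hydroxy-N-nitrosamine
    pattern_entry(
      "diazeniumdiolate", "searchable", "rare",
      "[OX2H1][NX3][NX2]=[OX1]", "graminine",
      pattern_graph(
        list(o_hydroxyl(), p_atom("N", arom = FALSE, xtot = 3),
             p_atom("N", arom = FALSE, xtot = 2), o_carbonyl()),
        p_bonds(1, 2, "-", 2, 3, "-", 3, 4, "="))),
    # exemplar: 2-nitrosophenol chromophores
    pattern_entry(
      "2-nitrosophenol", "searchable", "rare",
      "[OX2H1]c1ccccc1[NX2]=[OX1]", "2-nitrosophenol",
      pattern_graph(
        c(replicate(6, c_ar(), simplify = FALSE),
          list(o_hydroxyl(), p_atom("N", arom = FALSE, xtot = 2),
               o_carbonyl())),
        rbind(ring6(1), p_bonds(1, 7, "-", 2, 8, "-", 8, 9, "=")))),
    # exemplar: aerobactin; free carboxylate on a citrate core whose arm is
    # amide-linked (distinguishes chelating citrate cores from free citric
    # acid, which never triggers candidacy)
    pattern_entry(
      "carboxylate-in-citrate", "searchable", "common",
      paste0("[OX2H1][CX3](=[OX1])[CX4]([OX2H1])",
             "([CH2X4][CX3](=[OX1])[NX3])[CH2X4][CX3]=[OX1]"),
      "aerobactin",
      pattern_graph(
        list(o_hydroxyl(), p_atom("C", arom = FALSE, xtot = 3), o_carbonyl(),
             p_atom("C", arom = FALSE, xtot = 4), o_hydroxyl(),
             p_atom("C", arom = FALSE, xtot = 4, hmin = 2, hmax = 2),
             p_atom("C", arom = FALSE, xtot = 3), o_carbonyl(),
             p_atom("N", arom = FALSE, xtot = 3),
             p_atom("C", arom = FALSE, xtot = 4, hmin = 2, hmax = 2),
             p_atom("C", arom = FALSE, xtot = 3), o_carbonyl()),
        p_bonds(1, 2, "-", 2, 3, "=", 2, 4, "-", 4, 5, "-", 4, 6, "-",
                6, 7, "-", 7, 8, "=", 7, 9, "-", 4, 10, "-", 10, 11, "-",
                11, 12, "="))),
    # exemplar: aerobactin central carbon; alpha-hydroxycarboxylate in the
    # same amide-linked citrate context
    pattern_entry(
      "alpha-hydroxycarboxylate-in-citrate", "searchable", "common",
      paste0("[OX2H1][CX4]([CX3](=[OX1])[OX2H1])",
             "([CH2X4][CX3](=[OX1])[NX3])[CH2X4][CX3]=[OX1]"),
      "aerobactin",
      pattern_graph(
        list(o_hydroxyl(), p_atom("C", arom = FALSE, xtot = 4),
             p_atom("C", arom = FALSE, xtot = 3), o_carbonyl(), o_hydroxyl(),
             p_atom("C", arom = FALSE, xtot = 4, hmin = 2, hmax = 2),
             p_atom("C", arom = FALSE, xtot = 3), o_carbonyl(),
             p_atom("N", arom = FALSE, xtot = 3),
             p_atom("C", arom = FALSE, xtot = 4, hmin = 2, hmax = 2),
             p_atom("C", arom = FALSE, xtot = 3), o_carbonyl()),
        p_bonds(1, 2, "-", 2, 3, "-", 3, 4, "=", 3, 5, "-", 2, 6, "-",
                6, 7, "-", 7, 8, "=", 7, 9, "-", 2, 10, "-", 10, 11, "-",
                11, 12, "="))),
    # exemplar: quinolobactin; 8-hydroxyquinoline N,O-donor
    pattern_entry(
      "8-hydroxyquinoline", "searchable", "rare",
      "[OX2H1]c1cccc2cccnc12", "quinolobactin",
      pattern_graph(
        c(list(o_hydroxyl()),
          replicate(5, c_ar(), simplify = FALSE),   # atoms 2-6 (benzo)
          replicate(3, c_ar(), simplify = FALSE),   # atoms 7-9 (pyridine)
          list(p_atom("N", arom = TRUE, ring = TRUE), c_ar())),
        p_bonds(1, 2, "-", 2, 3, ":", 3, 4, ":", 4, 5, ":", 5, 6, ":",
                6, 7, ":", 7, 8, ":", 8, 9, ":", 9, 10, ":", 10, 11, ":",
                11, 2, ":", 11, 6, ":"))),
    ## -- common, excluded from the candidacy rule -------------------------
    # ubiquitous in primary metabolism (citric, malic, lactic acids...)
    pattern_entry(
      "alpha-hydroxycarboxylate", "common_excluded", "common",
      "[OX2H1][CX4][CX3](=[OX1])[OX2H1]", "citric acid",
      pattern_graph(
        list(o_hydroxyl(), p_atom("C", arom = FALSE, xtot = 4),
             p_atom("C", arom = FALSE, xtot = 3), o_carbonyl(),
             o_hydroxyl()),
        p_bonds(1, 2, "-", 2, 3, "-", 3, 4, "=", 3, 5, "-"))),
    pattern_entry(
      "carboxylate", "common_excluded", "common",
      "[CX3](=[OX1])[OX2H1]", "any free carboxylic acid",
      pattern_graph(
        list(p_atom("C", arom = FALSE, xtot = 3), o_carbonyl(),
             o_hydroxyl()),
        p_bonds(1, 2, "=", 1, 3, "-"))),
    ## -- modified vetoes (blocked chelating oxygens) ----------------------
    pattern_entry(
      "O-alkyl-hydroxamate", "modified_veto", "rare",
      "[CX3](=[OX1])[NX3][OX2][CX4]", "O-methylated hydroxamate",
      pattern_graph(
        list(p_atom("C", arom = FALSE, xtot = 3), o_carbonyl(),
             p_atom("N", arom = FALSE, xtot = 3), o_ether(),
             p_atom("C", arom = FALSE, xtot = 4)),
        p_bonds(1, 2, "=", 1, 3, "-", 3, 4, "-", 4, 5, "-"))),
    pattern_entry(
      "O-acyl-hydroxamate", "modified_veto", "rare",
      "[CX3](=[OX1])[NX3][OX2][CX3]=[OX1]", "O-acetylated hydroxamate",
      pattern_graph(
        list(p_atom("C", arom = FALSE, xtot = 3), o_carbonyl(),
             p_atom("N", arom = FALSE, xtot = 3), o_ether(),
             p_atom("C", arom = FALSE, xtot = 3), o_carbonyl()),
        p_bonds(1, 2, "=", 1, 3, "-", 3, 4, "-", 4, 5, "-", 5, 6, "="))),
    pattern_entry(
      "O-alkyl-catecholate", "modified_veto", "rare",
      "[CX4][OX2]c1ccccc1[OX2]", "guaiacol-type blocked catechol",
      pattern_graph(
        c(list(p_atom("C", arom = FALSE, xtot = 4), o_ether()),
          replicate(6, c_ar(), simplify = FALSE),
          list(p_atom("O", arom = FALSE, xtot = 2))),
        rbind(p_bonds(1, 2, "-", 2, 3, "-"), ring6(3),
              p_bonds(4, 9, "-")))),
    pattern_entry(
      "O-acyl-catecholate", "modified_veto", "rare",
      "[OX1]=[CX3][OX2]c1ccccc1[OX2]", "O-acylated catechol",
      pattern_graph(
        c(list(o_carbonyl(), p_atom("C", arom = FALSE, xtot = 3),
               o_ether()),
          replicate(6, c_ar(), simplify = FALSE),
          list(p_atom("O", arom = FALSE, xtot = 2))),
        rbind(p_bonds(1, 2, "=", 2, 3, "-", 3, 4, "-"), ring6(4),
              p_bonds(5, 10, "-")))),
    pattern_entry(
      "O-alkyl-phenolate", "modified_veto", "rare",
      "[CX4][OX2]c1ccccc1[CX3]=[OX1]", "2-methoxyphenyl ketone/amide",
      pattern_graph(
        c(list(p_atom("C", arom = FALSE, xtot = 4), o_ether()),
          replicate(6, c_ar(), simplify = FALSE),
          list(p_atom("C", arom = FALSE, xtot = 3), o_carbonyl())),
        rbind(p_bonds(1, 2, "-", 2, 3, "-"), ring6(3),
              p_bonds(4, 9, "-", 9, 10, "=")))),
    pattern_entry(
      "O-acyl-phenolate", "modified_veto", "rare",
      "[OX1]=[CX3][OX2]c1ccccc1[CX3]=[OX1]", "O-acylated salicyl carbonyl",
      pattern_graph(
        c(list(o_carbonyl(), p_atom("C", arom = FALSE, xtot = 3),
               o_ether()),
          replicate(6, c_ar(), simplify = FALSE),
          list(p_atom("C", arom = FALSE, xtot = 3), o_carbonyl())),
        rbind(p_bonds(1, 2, "=", 2, 3, "-", 3, 4, "-"), ring6(4),
              p_bonds(5, 10, "-", 10, 11, "=")))),
    pattern_entry(
      "O-alkyl-hydroxyphenylazoline", "modified_veto", "rare",
      "[CX4][OX2]c1ccccc1[CX3]2=[NX2][CX4][CX4][O,S]2",
      "O-methylated hydroxyphenyl-oxazoline/thiazoline",
      pattern_graph(
        c(list(p_atom("C", arom = FALSE, xtot = 4), o_ether()),
          replicate(6, c_ar(), simplify = FALSE),
          list(p_atom("C", arom = FALSE, xtot = 3),
               p_atom("N", arom = FALSE, xtot = 2),
               p_atom("C", arom = FALSE, xtot = 4),
               p_atom("C", arom = FALSE, xtot = 4),
               p_atom(c("O", "S"), arom = FALSE, heavy = 2, hmax = 0))),
        rbind(p_bonds(1, 2, "-", 2, 3, "-"), ring6(3),
              p_bonds(4, 9, "-", 9, 10, "=", 10, 11, "-", 11, 12, "-",
                      12, 13, "-", 13, 9, "-")))),
    pattern_entry(
      "O-alkyl-2-nitrosophenol", "modified_veto", "rare",
      "[CX4][OX2]c1ccccc1[NX2]=[OX1]", "O-alkylated 2-nitrosophenol",
      pattern_graph(
        c(list(p_atom("C", arom = FALSE, xtot = 4), o_ether()),
          replicate(6, c_ar(), simplify = FALSE),
          list(p_atom("N", arom = FALSE, xtot = 2), o_carbonyl())),
        rbind(p_bonds(1, 2, "-", 2, 3, "-"), ring6(3),
              p_bonds(4, 9, "-", 9, 10, "="))))
  )
}

PATTERN_REGISTRY_VERSION <- "1.0"

#' Load the functional-group pattern registry
#'
#' Returns the default registry of siderophore functional-group patterns:
#' 15 searchable iron-coordinating groups, 2 common groups excluded from the
#' candidacy rule for their ubiquity (alpha-hydroxycarboxylate and plain
#' carboxylate, which are still counted for statistics), and 8 modified-veto
#' groups whose blocked oxygens cannot coordinate iron.
#'
#' @param override_path Optional path to a TSV with columns
#'   `group_name`, `category`, `smarts`, `rarity`.  Its rows are appended to
#'   the default registry (e.g. to add an extra searchable group).  Appended
#'   patterns are matched with the OpenBabel SMARTS engine and report counts
#'   but not matched atom sets.
#' @return An object of class `pattern_registry`: a list of pattern entries,
#'   each with `group_name`, `category` (one of `searchable`,
#'   `common_excluded`, `modified_veto`), `rarity`, `smarts`, `exemplar`,
#'   and (for built-in entries) a pattern `graph`.
#' @examples
#' reg <- load_default_patterns()
#' table(vapply(reg, `[[`, "", "category"))
#' @export
load_default_patterns <- function(override_path = NULL) {
  entries <- default_pattern_list()
  if (!is.null(override_path)) {
    tab <- read.delim(override_path, sep = "\t", stringsAsFactors = FALSE)
    assert_cols(tab, c("group_name", "category", "smarts", "rarity"),
                "pattern override table")
    bad_cat <- setdiff(tab$category,
                       c("searchable", "common_excluded", "modified_veto"))
    if (length(bad_cat) > 0) {
      stop("unknown pattern category: ", paste(bad_cat, collapse = ", "))
    }
    probe <- ChemmineR::smiles2sdf(c(probe = "CCO"))
    for (i in seq_len(nrow(tab))) {
      ok <- tryCatch({
        ChemmineR::smartsSearchOB(probe, tab$smarts[i], uniqueMatches = TRUE)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) {
        stop(sprintf("pattern '%s' does not compile: %s",
                     tab$group_name[i], tab$smarts[i]), call. = FALSE)
      }
      entries[[length(entries) + 1L]] <-
        pattern_entry(tab$group_name[i], tab$category[i], tab$rarity[i],
                      tab$smarts[i], "user override", graph = NULL)
    }
  }
  nm <- vapply(entries, `[[`, "", "group_name")
  if (anyDuplicated(nm)) {
    stop("duplicate group_name in pattern registry: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  structure(entries, class = "pattern_registry",
            version = PATTERN_REGISTRY_VERSION)
}

#' @export
print.pattern_registry <- function(x, ...) {
  cat ("<pattern_registry> version", attr(x, "version"), "-",
       length(x), "patterns\n")
  cats <- vapply(x, `[[`, "", "category")
  print(table(cats))
  invisible(x)
}

pattern_names <- function(patterns, category = NULL) {
  nm <- vapply(patterns, `[[`, "", "group_name")
  if (is.null(category)) return(nm)
  nm[vapply(patterns, `[[`, "", "category") %in% category]
}

#' Write a pattern registry to a TSV file
#'
#' @param patterns A `pattern_registry`.
#' @param path Output path; columns `group_name`, `category`, `smarts`,
#'   `rarity` (UTF-8, tab-separated).
#' @return `path`, invisibly.
#' @export
write_patterns <- function(patterns, path) {
  df <- data.frame(
    group_name = vapply(patterns, `[[`, "", "group_name"),
    category = vapply(patterns, `[[`, "", "category"),
    smarts = vapply(patterns, `[[`, "", "smarts"),
    rarity = vapply(patterns, `[[`, "", "rarity"),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
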