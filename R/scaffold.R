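AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

ROLES <- c("acceptor", "hbond_partner", "donor", "counterion",
           "release1", "release2", "schiff_lysine")

#' Scaffold specification for synthetic rhodopsin references
#'
#' Defines the shared backbone on which synthetic rhodopsin homologs are
#' built: a sequence length and a map from functional role to scaffold
#' position. The default site map uses the numbering of the N2098R-type
#' pump (proton acceptor Asp74, hydrogen-bond partner at 78, donor at 85,
#' proton-release pair 182/192, Schiff-base counterion 200, Schiff-base
#' lysine 204); scaffold coordinates stand in for bacteriorhodopsin-style
#' numbering in synthetic work.
#'
#' @param length residue count of the scaffold (default 250).
#' @param site_map named integer vector mapping every role in
#'   `acceptor, hbond_partner, donor, counterion, release1, release2,
#'   schiff_lysine` to a distinct 1-based position within the scaffold.
#' @param seed RNG seed used to draw the scaffold background residues.
#' @return An object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(length = 250L,
                          site_map = c(acceptor = 74L, hbond_partner = 78L,
                                       donor = 85L, counterion = 200L,
                                       release1 = 182L, release2 = 192L,
                                       schiff_lysine = 204L),
                          seed = 1L) {
  length <- as.integer(length)
  if (length < 1L) stop("scaffold length must be positive")
  if (!setequal(names(site_map), ROLES))
    stop("site_map must name exactly the roles: ", paste(ROLES, collapse = ", "))
  site_map <- vapply(site_map[ROLES], as.integer, integer(1))
  if (anyDuplicated(site_map))
    stop("site_map positions overlap: all mapped positions must be distinct")
  if (any(site_map < 1L | site_map > length))
    stop("site_map positions must lie in [1, length]")
  structure(list(length = length, site_map = site_map, seed = as.integer(seed)),
            class = "scaffold_spec")
}

#' Clade template for synthetic reference generation
#'
#' A clade is spawned from the common scaffold by substituting residues at a
#' clade-specific expected rate (`divergence`, substitutions per site), with
#' the functional sites (motif triplet, counterion, release pair, Schiff
#' lysine) held fixed. Decoy templates instead ablate the Schiff lysine and
#' are drawn at divergence 1 (unrelated background).
#'
#' @param clade_label one of `"XLR"`, `"NaR"`, `"XeR"`, `"CyHR"`, `"CyR"`,
#'   `"decoy"`.
#' @param motif_triplet three residue letters planted at the
#'   acceptor / hbond-partner / donor sites, e.g. `"DTD"` or `"DTE"`.
#' @param divergence expected substitutions per site from the scaffold, in
#'   `[0, 0.6]` (decoys are forced to 1).
#' @param habitat_weights named numeric weights over
#'   `marine, freshwater, saline, NA`; need not be normalised.
#' @return An object of class `clade_template`.
#' @export
clade_template <- function(clade_label, motif_triplet, divergence = 0.25,
                           habitat_weights = c(marine = 0, freshwater = 0.7,
                                               saline = 0.2, "NA" = 0.1)) {
  clade_label <- match.arg(clade_label, c("XLR", "NaR", "XeR", "CyHR", "CyR", "decoy"))
  if (clade_label != "decoy") {
    if (nchar(motif_triplet) != 3L || !all(strsplit(motif_triplet, "")[[1]] %in% AA20))
      stop("motif_triplet must be three amino-acid letters")
    if (divergence < 0 || divergence > 0.6)
      stop("divergence must lie in [0, 0.6]")
  } else {
    divergence <- 1
  }
  hw <- c(marine = 0, freshwater = 0, saline = 0, "NA" = 0)
  hw[names(habitat_weights)] <- habitat_weights
  if (any(hw < 0) || sum(hw) <= 0) stop("habitat_weights must be non-negative with positive sum")
  structure(list(clade_label = clade_label, motif_triplet = motif_triplet,
                 divergence = divergence, habitat_weights = hw / sum(hw)),
            class = "clade_template")
}

#' Default clade templates
#'
#' One template per reference clade, with the helix-C motif the field
#' associates with each pump type: CyR carries DTD (the dominant motif of the
#' cyanorhodopsin clade; three members carry DTE instead), XLR carries DTE
#' (GR-like outward proton pump), NaR the NDQ sodium-pump motif, CyHR the
#' TSD chloride-pump motif, and XeR a DTA inward-pump-like motif. CyR habitat
#' weights put zero mass on marine, mirroring the non-marine composition of
#' that clade; this is a generator default, not a claim about real genomes.
#'
#' @param include_dte if `TRUE`, append a second CyR-like template carrying
#'   the DTE motif variant.
#' @return A list of [clade_template()] objects.
#' @export
default_clade_templates <- function(include_dte = FALSE) {
  tpl <- list(
    clade_template("CyR",  "DTD", divergence = 0.25,
                   habitat_weights = c(freshwater = 0.7, saline = 0.2, "NA" = 0.1)),
    clade_template("CyHR", "TSD", divergence = 0.25,
                   habitat_weights = c(freshwater = 0.5, saline = 0.4, "NA" = 0.1)),
    clade_template("XeR",  "DTA", divergence = 0.25,
                   habitat_weights = c(freshwater = 0.6, saline = 0.2, marine = 0.2)),
    clade_template("XLR",  "DTE", divergence = 0.25,
                   habitat_weights = c(freshwater = 0.5, marine = 0.3, saline = 0.2)),
    clade_template("NaR",  "NDQ", divergence = 0.25,
                   habitat_weights = c(marine = 0.6, saline = 0.4))
  )
  tpl
}

protected_sites <- function(spec) unname(spec$site_map)

draw_scaffold <- function(spec) {
  seq <- with_seed(spec$seed, sample(AA20, spec$length, replace = TRUE))
  seq[spec$site_map[["counterion"]]] <- "D"
  seq[spec$site_map[["release1"]]] <- "E"
  seq[spec$site_map[["release2"]]] <- "E"
  seq[spec$site_map[["schiff_lysine"]]] <- "K"
  seq
}

plant_sites <- function(seq, spec, motif_triplet) {
  m <- strsplit(motif_triplet, "")[[1]]
  seq[spec$site_map[["acceptor"]]] <- m[1]
  seq[spec$site_map[["hbond_partner"]]] <- m[2]
  seq[spec$site_map[["donor"]]] <- m[3]
  seq[spec$site_map[["counterion"]]] <- "D"
  seq[spec$site_map[["release1"]]] <- "E"
  seq[spec$site_map[["release2"]]] <- "E"
  seq[spec$site_map[["schiff_lysine"]]] <- "K"
  seq
}

# Clade founders are a pure function of (spec, template): references and
# planted genome genes generated in separate calls share the same founder,
# which is what gives within-clade identity its margin over between-clade.
clade_founder <- function(spec, scaffold, tpl) {
  founder_seed <- substream_seed(spec$seed, paste0("founder_", tpl$clade_label))
  with_seed(founder_seed,
            plant_sites(mutate_seq(scaffold, tpl$divergence, protected_sites(spec)),
                        spec, tpl$motif_triplet))
}

# Substitute residues at per-site probability `rate`, never touching
# `protect` positions; substitutions only, so coordinates stay exact.
mutate_seq <- function(seq, rate, protect) {
  if (rate <= 0) return(seq)
  hit <- runif(length(seq)) < rate
  hit[protect] <- FALSE
  for (i in which(hit)) seq[i] <- sample(setdiff(AA20, seq[i]), 1L)
  seq
}

insert_loops <- function(seq, protect, max_len = 5L) {
  # indel stress: insert one short loop at a position away from mapped sites
  ok <- setdiff(seq_along(seq), unlist(lapply(protect, function(p) (p - 1L):(p + 1L))))
  at <- sample(ok, 1L)
  loop <- sample(AA20, sample.int(max_len, 1L), replace = TRUE)
  append(seq, loop, after = at)
}

#' Generate a clade-labelled synthetic reference panel
#'
#' Spawns `n_refs_per_clade` members per clade template. Each clade has a
#' founder drawn from the scaffold at the template's divergence; members are
#' drawn from the founder at one third of that divergence, so within-clade
#' identity exceeds between-clade identity. Functional sites (motif triplet,
#' counterion, release pair, Schiff lysine) are never mutated; decoy
#' templates yield unrelated sequences with the Schiff lysine ablated.
#'
#' @param spec a [scaffold_spec()].
#' @param templates list of [clade_template()] with distinct clade labels.
#' @param n_refs_per_clade members per clade (at least 1).
#' @param seed RNG seed.
#' @param indel_stress if `TRUE`, each member additionally receives one short
#'   (up to 5 residue) insertion away from the mapped sites.
#' @return A list with `sequences` (named character vector of protein
#'   sequences) and `truth` (data.frame: `protein_id`, `is_rhodopsin`,
#'   `clade_label`, `motif_triplet`).
#' @export
gen_scaffold_refs <- function(spec, templates, n_refs_per_clade = 3L, seed = 1L,
                              indel_stress = FALSE) {
  stopifnot(inherits(spec, "scaffold_spec"))
  if (n_refs_per_clade < 1L) stop("n_refs_per_clade must be at least 1")
  labels <- vapply(templates, function(t) t$clade_label, character(1))
  if (anyDuplicated(labels)) stop("templates must have distinct clade labels")
  scaffold <- draw_scaffold(spec)
  protect <- protected_sites(spec)
  seqs <- character(0); truth <- list()
  with_seed(seed, {
    for (tpl in templates) {
      decoy <- tpl$clade_label == "decoy"
      if (decoy) {
        for (i in seq_len(n_refs_per_clade)) {
          s <- sample(AA20, spec$length, replace = TRUE)
          s[spec$site_map[["schiff_lysine"]]] <- sample(setdiff(AA20, "K"), 1L)
          id <- sprintf("decoy_%03d", i)
          seqs[id] <- paste(s, collapse = "")
          truth[[id]] <- data.frame(protein_id = id, is_rhodopsin = FALSE,
                                    clade_label = "decoy", motif_triplet = NA_character_)
        }
        next
      }
      founder <- clade_founder(spec, scaffold, tpl)
      for (i in seq_len(n_refs_per_clade)) {
        s <- mutate_seq(founder, tpl$divergence / 3, protect)
        if (indel_stress) s <- insert_loops(s, protect)
        id <- sprintf("%s_ref_%02d", tpl$clade_label, i)
        seqs[id] <- paste(s, collapse = "")
        truth[[id]] <- data.frame(protein_id = id, is_rhodopsin = TRUE,
                                  clade_label = tpl$clade_label,
                                  motif_triplet = tpl$motif_triplet)
      }
    }
  })
  list(sequences = seqs, truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate a synthetic genome set with planted rhodopsins and decoys
#'
#' Emulates a genome survey: each genome carries a habitat label drawn from
#' its gene templates' habitat weights, a configurable number of planted
#' rhodopsin genes (clades cycled over `templates`), and unrelated decoy
#' proteins (random sequences with the Schiff-lysine site ablated). The truth
#' table records ground truth for every emitted protein exactly once.
#'
#' @param spec a [scaffold_spec()].
#' @param templates list of non-decoy [clade_template()]s to plant.
#' @param n_genomes number of genomes (at least 1).
#' @param genes_per_genome integer vector recycled over genomes: planted
#'   rhodopsin genes per genome.
#' @param decoys_per_genome decoy proteins per genome.
#' @param seed RNG seed.
#' @return A list of class `synthetic_genome_set`: `proteomes` (named list of
#'   named sequence vectors per genome), `genomes` (data.frame: `genome_id`,
#'   `subclade`, `habitat`, `diox1_present`), and `truth` (per-protein truth
#'   table with `genome_id`).
#' @export
gen_genome_set <- function(spec, templates, n_genomes = 10L,
                           genes_per_genome = 1L, decoys_per_genome = 5L,
                           seed = 1L) {
  stopifnot(inherits(spec, "scaffold_spec"))
  if (length(templates) == 0L) stop("templates must be non-empty")
  if (n_genomes < 1L) stop("n_genomes must be at least 1")
  scaffold <- draw_scaffold(spec)
  protect <- protected_sites(spec)
  genes_per_genome <- rep_len(as.integer(genes_per_genome), n_genomes)
  founders <- list()
  proteomes <- list(); genomes <- list(); truth <- list()
  for (tpl in templates)
    founders[[tpl$clade_label]] <- clade_founder(spec, scaffold, tpl)
  with_seed(seed, {
    k <- 0L
    for (g in seq_len(n_genomes)) {
      gid <- sprintf("genome_%03d", g)
      prot <- character(0)
      tpl0 <- templates[[(g - 1L) %% length(templates) + 1L]]
      habitat <- sample(names(tpl0$habitat_weights), 1L, prob = tpl0$habitat_weights)
      for (j in seq_len(genes_per_genome[g])) {
        k <- k + 1L
        tpl <- templates[[(k - 1L) %% length(templates) + 1L]]
        s <- mutate_seq(founders[[tpl$clade_label]], tpl$divergence / 3, protect)
        id <- sprintf("%s_gene_%04d", gid, j)
        prot[id] <- paste(s, collapse = "")
        truth[[id]] <- data.frame(genome_id = gid, protein_id = id,
                                  is_rhodopsin = TRUE, clade_label = tpl$clade_label,
                                  motif_triplet = tpl$motif_triplet)
      }
      for (j in seq_len(decoys_per_genome)) {
        s <- sample(AA20, spec$length, replace = TRUE)
        s[spec$site_map[["schiff_lysine"]]] <- sample(setdiff(AA20, "K"), 1L)
        id <- sprintf("%s_decoy_%04d", gid, j)
        prot[id] <- paste(s, collapse = "")
        truth[[id]] <- data.frame(genome_id = gid, protein_id = id,
                                  is_rhodopsin = FALSE, clade_label = "decoy",
                                  motif_triplet = NA_character_)
      }
      proteomes[[gid]] <- prot
      genomes[[gid]] <- data.frame(genome_id = gid,
                                   subclade = sample(c("B", "D", "E"), 1L),
                                   habitat = habitat, diox1_present = TRUE)
    }
  })
  structure(list(proteomes = proteomes,
                 genomes = do.call(rbind, c(genomes, list(make.row.names = FALSE))),
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE)))),
            class = "synthetic_genome_set")
}
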