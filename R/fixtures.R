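## Shipped study system: an 18-taxon bat phylogeny (15 bats, 3 outgroups)
## with the lineage classes used throughout the documentation and tests.
##
## Clades: Yangochiroptera (6 laryngeal echolocators), Rhinolophoidea (6
## laryngeal echolocators within Yinpterochiroptera), Pteropodidae (3
## non-echolocating Old World fruit bats), plus dog, rabbit and human as
## outgroups.  Branch classes: a = bat stem, b = Yangochiroptera stem,
## c = Rhinolophoidea stem, d = Yinpterochiroptera stem, e = Pteropodidae
## stem.  Branch lengths are in expected substitutions per site and are
## deliberately short: the channel protein studied is highly conserved
## (largest pairwise distance below 0.1).

.BAT_CLADES <- list(
  yango = c("Myotis_laniger", "Myotis_fimbriatus", "Myotis_lucifugus",
            "Pipistrellus_abramus", "Tylonycteris_pachypus",
            "Tadarida_teniotis"),
  rhino = c("Megaderma_spasma", "Hipposideros_armiger",
            "Hipposideros_larvatus", "Aselliscus_stoliczkanus",
            "Rhinolophus_thomasi", "Rhinolophus_macrotis"),
  ptero = c("Cynopterus_sphinx", "Pteropus_vampyrus",
            "Rousettus_leschenaultii"),
  outgroup = c("Canis_familiaris", "Oryctolagus_cuniculus", "Homo_sapiens"))

.yangoNwk <- paste0(
  "((((Myotis_laniger:0.004,Myotis_fimbriatus:0.004):0.003,",
  "Myotis_lucifugus:0.007):0.008,(Pipistrellus_abramus:0.012,",
  "Tylonycteris_pachypus:0.012):0.003):0.004,Tadarida_teniotis:0.019)")
.rhinoNwk <- paste0(
  "(Megaderma_spasma:0.016,(((Hipposideros_armiger:0.005,",
  "Hipposideros_larvatus:0.005):0.003,Aselliscus_stoliczkanus:0.008):0.004,",
  "(Rhinolophus_thomasi:0.006,Rhinolophus_macrotis:0.006):0.006):0.004)")
.pteroNwk <- paste0(
  "(Cynopterus_sphinx:0.008,(Pteropus_vampyrus:0.007,",
  "Rousettus_leschenaultii:0.007):0.002)")
.outNwk <- paste0(
  "(Canis_familiaris:0.030,(Homo_sapiens:0.028,",
  "Oryctolagus_cuniculus:0.028):0.004)")

#' Bundled bat species tree and conflicting protein-tree topology
#'
#' `batSpeciesTree()` returns the rooted 18-taxon species phylogeny with
#' branch classes `a`--`e` attached (bat stem, Yangochiroptera stem,
#' Rhinolophoidea stem, Yinpterochiroptera stem, Old World fruit bat
#' stem).  In the species tree the two laryngeal-echolocating clades
#' (Yangochiroptera and Rhinolophoidea) are paraphyletic: Rhinolophoidea
#' groups with the fruit bats.  `batProteinTree()` returns the alternative
#' topology in which all echolocators form one clade and the fruit bats
#' fall outside, the arrangement a hearing-gene protein tree shows when
#' sites evolve in parallel with high-frequency hearing.
#'
#' @param labeled return a [LabeledPhylo-class] (default) or a bare
#'   `phylo`.
#' @return a [LabeledPhylo-class] or `phylo`.
#' @export
batSpeciesTree <- function(labeled = TRUE) {
  nwk <- sprintf("(%s:0.006,(%s:0.010,(%s:0.010,%s:0.003):0.001):0.002);",
                 .outNwk, .yangoNwk, .rhinoNwk, .pteroNwk)
  tr <- ape::read.tree(text = nwk)
  if (!labeled) return(tr)
  cl <- .BAT_CLADES
  labeledPhylo(tr, list(
    a = c(cl$yango, cl$rhino, cl$ptero),
    b = cl$yango, c = cl$rhino,
    d = c(cl$rhino, cl$ptero), e = cl$ptero))
}

#' @rdname batSpeciesTree
#' @export
batProteinTree <- function(labeled = FALSE) {
  nwk <- sprintf("(%s:0.006,(%s:0.003,(%s:0.010,%s:0.010):0.004):0.002);",
                 .outNwk, .pteroNwk, .yangoNwk, .rhinoNwk)
  tr <- ape::read.tree(text = nwk)
  if (!labeled) return(tr)
  cl <- .BAT_CLADES
  labeledPhylo(tr, list(
    a = c(cl$yango, cl$rhino, cl$ptero),
    b = cl$yango, c = cl$rhino, e = cl$ptero))
}

#' @rdname batSpeciesTree
#' @details `batClades()` returns the tip sets of the named clades;
#'   `batLineagePairs()` the branch-class pairs tested for parallel
#'   substitution (the two echolocator stem branches).
#' @export
batClades <- function() .BAT_CLADES

#' @rdname batSpeciesTree
#' @export
batLineagePairs <- function() list(echolocatorStems = c("b", "c"))
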