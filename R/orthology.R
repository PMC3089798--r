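# Ortholog-anchored cross-species comparison of differential-expression
# calls: conserved / divergent / species-specific / partial categories,
# pairwise overlaps and three-way Venn partitions.

#' Map per-species DE calls onto ortholog groups
#'
#' For each ortholog group, determines the per-species status (`up`,
#' `down`, `ns`, or `absent` when the gene is not represented on that
#' species' platform or the group lacks a member there) and assigns a
#' category:
#' \itemize{
#'   \item `conserved`: all represented species significant, same sign,
#'     with at least two species represented;
#'   \item `divergent`: significant calls in at least two species with
#'     opposite signs;
#'   \item `specific`: exactly one significant species among >= 2
#'     represented;
#'   \item `partial`: >= 2 significant same-sign species but at least one
#'     represented species not significant;
#'   \item `none`: no significant species (or fewer than two represented,
#'     where cross-species comparison is undefined).
#' }
#'
#' @param status_by_species named list (one element per species) of
#'   data.frames with columns `gene_id` and `direction`
#'   (`up`/`down`/`ns`), e.g. from [de_call_summary()].
#' @param orthologs validated ortholog table (`group_id`, `species`,
#'   `gene_id`).
#' @param universes named list of character vectors: the gene ids present
#'   on each species' platform. Species set is taken from this list.
#' @return data.frame with `group_id`, one `status_<species>` column per
#'   species, and `category`.
#' @export
map_calls <- function(status_by_species, orthologs, universes) {
  validate_ortholog_table(orthologs)
  species <- names(universes)
  if (is.null(species) || length(species) < 2)
    stop("need named platform universes for at least two species")
  groups <- sort(unique(orthologs$group_id))
  status <- matrix("absent", length(groups), length(species),
                   dimnames = list(groups, species))
  for (s in species) {
    members <- orthologs[orthologs$species == s, ]
    members <- members[members$gene_id %in% universes[[s]], ]
    if (!nrow(members)) next
    dirs <- rep("ns", nrow(members))
    calls <- status_by_species[[s]]
    if (!is.null(calls)) {
      idx <- match(members$gene_id, calls$gene_id)
      found <- !is.na(idx)
      dirs[found] <- calls$direction[idx[found]]
    }
    status[members$group_id, s] <- dirs
  }
  category <- apply(status, 1, classify_group_status)
  out <- data.frame(group_id = groups, status,
                    category = unname(category),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[seq_along(species) + 1L] <- paste0("status_", species)
  out
}

#' Categorise one ortholog group from per-species statuses
#'
#' @param status character vector over species with values `up`, `down`,
#'   `ns`, `absent`.
#' @return one of `conserved`, `divergent`, `specific`, `partial`, `none`.
#' @export
classify_group_status <- function(status) {
  represented <- status != "absent"
  sig <- status %in% c("up", "down")
  n_rep <- sum(represented)
  n_sig <- sum(sig)
  if (n_rep < 2 || n_sig == 0) return("none")
  signs <- unique(status[sig])
  if (length(signs) > 1) return("divergent")
  if (n_sig == 1) return("specific")
  if (n_sig == n_rep) return("conserved")
  "partial"
}

#' Pairwise ortholog overlap between two platforms
#'
#' Counts ortholog groups represented on both platforms and, of those, the
#' groups significant (non-`ns`) in both species.
#'
#' @param cross_calls output of [map_calls()].
#' @param species_a,species_b the pair to compare.
#' @return named integer vector `c(n_shared_orthologs, n_shared_de)`.
#' @export
pairwise_overlap <- function(cross_calls, species_a, species_b) {
  sa <- paste0("status_", species_a); sb <- paste0("status_", species_b)
  if (!all(c(sa, sb) %in% names(cross_calls)))
    stop("unknown species: ",
         paste(setdiff(c(species_a, species_b),
                       sub("^status_", "",
                           grep("^status_", names(cross_calls),
                                value = TRUE))), collapse = ", "))
  a <- cross_calls[[sa]]; b <- cross_calls[[sb]]
  shared <- a != "absent" & b != "absent"
  de_both <- shared & a %in% c("up", "down") & b %in% c("up", "down")
  c(n_shared_orthologs = sum(shared), n_shared_de = sum(de_both))
}

#' Three-way Venn partition of DE ortholog groups
#'
#' Restricted to groups represented on all three platforms, partitions the
#' groups significant in at least one species into the seven disjoint Venn
#' regions.
#'
#' @param cross_calls output of [map_calls()].
#' @param species character vector of exactly three species.
#' @return named integer vector with regions `A_only`, `B_only`, `C_only`,
#'   `AB`, `AC`, `BC`, `ABC` (A, B, C in the order given) and a `species`
#'   attribute.
#' @export
venn_partition <- function(cross_calls, species) {
  if (length(species) != 3) stop("venn_partition needs exactly 3 species")
  cols <- paste0("status_", species)
  if (!all(cols %in% names(cross_calls)))
    stop("unknown species in cross_calls: ",
         paste(species[!cols %in% names(cross_calls)], collapse = ", "))
  st <- as.matrix(cross_calls[, cols])
  on_all <- rowSums(st != "absent") == 3
  de <- st[on_all, , drop = FALSE] == "up" | st[on_all, , drop = FALSE] == "down"
  key <- paste0(de[, 1] + 0, de[, 2] + 0, de[, 3] + 0)
  regions <- c(A_only = "100", B_only = "010", C_only = "001",
               AB = "110", AC = "101", BC = "011", ABC = "111")
  out <- vapply(regions, function(r) sum(key == r), integer(1))
  names(out) <- names(regions)
  attr(out, "species") <- species
  out
}

#' Shared differentially expressed fraction, to one decimal
#'
#' Percentage of shared orthologs differentially expressed in both species
#' of a pair; same rounding contract as [response_percentage()].
#'
#' @param n_shared_de,n_shared_orthologs counts.
#' @return percentage with one decimal.
#' @export
shared_fraction <- function(n_shared_de, n_shared_orthologs) {
  response_percentage(n_shared_de, n_shared_orthologs)
}
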