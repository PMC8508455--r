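#' Damage scoring parameters
#'
#' Bundles the constants of the direct and indirect strand-break models
#' and of the complexity classification. The defaults are the calibrated
#' damage-parameter set for the fibroblast study: an effective direct
#' radius of 3.5 A around sugar/phosphate, the linear 5-37.5 eV induction
#' law, a 40.5% break probability per OH-backbone reaction, a 9 nm radical
#' kill distance, a 5 ns chemical stage in 0.5 ns windows, 10 bp DSB
#' pairing distance, 100 bp fragment gap and a 10 kbp distant-DSB
#' threshold.
#'
#' @param R_direct_nm effective radius around backbone centres within
#'   which an energy deposit counts toward a site, nm.
#' @param E_lower_eV,E_higher_eV linear damage-probability thresholds, eV.
#' @param P_OH probability that an OH-backbone reaction induces an SSB.
#' @param d_kill_nm radical kill distance, nm.
#' @param T_chem_ns chemical stage end time, ns.
#' @param dt_max_ns maximum IRT synchronisation window, ns.
#' @param d_DSB_bp opposite-strand pairing distance for a DSB, bp.
#' @param d_s_bp fragment gap defining complex damage, bp.
#' @param distant_DSB_bp separation below which neighbouring DSBs merge
#'   into one detectable cluster, bp.
#' @return a `damage_params` list.
#' @export
damage_params <- function(R_direct_nm = 0.35, E_lower_eV = 5,
                          E_higher_eV = 37.5, P_OH = 0.405,
                          d_kill_nm = 9, T_chem_ns = 5, dt_max_ns = 0.5,
                          d_DSB_bp = 10L, d_s_bp = 100L,
                          distant_DSB_bp = 10000L) {
  if (E_lower_eV >= E_higher_eV) stop("E_lower must be below E_higher")
  if (P_OH < 0 || P_OH > 1) stop("P_OH must be in [0, 1]")
  if (d_kill_nm < 0) stop("d_kill must be >= 0")
  if (d_DSB_bp >= d_s_bp) stop("d_DSB must be below d_s")
  structure(list(R_direct_nm = R_direct_nm, E_lower_eV = E_lower_eV,
                 E_higher_eV = E_higher_eV, P_OH = P_OH,
                 d_kill_nm = d_kill_nm, T_chem_ns = T_chem_ns,
                 dt_max_ns = dt_max_ns, d_DSB_bp = as.integer(d_DSB_bp),
                 d_s_bp = as.integer(d_s_bp),
                 distant_DSB_bp = as.integer(distant_DSB_bp)),
            class = "damage_params")
}

#' Linear direct-damage probability
#'
#' Probability that an accumulated energy `E` at one backbone site induces
#' a break: 0 up to `E_lower`, rising linearly to 1 at `E_higher`.
#'
#' @param E accumulated energy per site, eV (vectorised).
#' @param params a [damage_params()].
#' @return break probabilities in `[0, 1]`.
#' @export
direct_break_probability <- function(E, params = damage_params()) {
  pmin(pmax((E - params$E_lower_eV) /
              (params$E_higher_eV - params$E_lower_eV), 0), 1)
}

#' Score direct strand breaks from energy deposits
#'
#' A deposit counts toward a backbone site (chromosome, strand, bp) when
#' it lies within `R_direct` of that site's sugar or phosphate centre; a
#' deposit close to both moieties of the same site counts once, and a
#' deposit within reach of several sites contributes its full energy to
#' each. Per site the accumulated energy is converted to a break with the
#' linear probability law and a single uniform draw.
#'
#' @param deposits deposit data frame ([generate_deposits()]).
#' @param molecules molecular volumes covering the deposits' region.
#' @param params a [damage_params()].
#' @param moiety_index optional precomputed [build_moiety_index()] over
#'   `molecules`.
#' @return strand-break data frame: `chromosome`, `strand`, `bp`,
#'   `source = "direct"`, `primary_id`.
#' @export
score_direct <- function(deposits, molecules, params = damage_params(),
                         moiety_index = NULL) {
  empty <- data.frame(chromosome = integer(), strand = integer(),
                      bp = integer(), source = character(),
                      primary_id = integer())
  if (nrow(deposits) == 0) return(empty)
  if (is.null(moiety_index)) moiety_index <- build_moiety_index(molecules)
  bb <- molecules[moiety_index$rows$backbone, , drop = FALSE]
  if (nrow(bb) == 0) return(empty)
  tree <- moiety_index$trees$backbone
  hits <- query_radius(tree, as.matrix(deposits[, c("x", "y", "z")]),
                       params$R_direct_nm)
  nh <- lengths(hits)
  if (sum(nh) == 0) return(empty)
  di <- rep(seq_len(nrow(deposits)), nh)
  mi <- unlist(hits)
  site <- data.frame(deposit = di,
                     chromosome = bb$chromosome[mi],
                     strand = bb$strand[mi],
                     bp = bb$bp[mi],
                     energy = deposits$energy_eV[di],
                     primary_id = deposits$primary_id[di])
  # one contribution per (deposit, site) even if both moieties are in range
  site <- unique(site)
  key <- paste(site$primary_id, site$chromosome, site$strand, site$bp,
               sep = "|")
  esum <- rowsum(site$energy, key)             # groups sorted by key
  first <- site[!duplicated(key), , drop = FALSE]
  first <- first[order(key[!duplicated(key)]), , drop = FALSE]
  p <- direct_break_probability(as.numeric(esum[, 1]), params)
  broke <- runif(length(p)) < p
  out <- data.frame(chromosome = first$chromosome[broke],
                    strand = first$strand[broke],
                    bp = first$bp[broke],
                    source = rep("direct", sum(broke)),
                    primary_id = first$primary_id[broke])
  rownames(out) <- NULL
  out
}

#' Score indirect strand breaks from OH backbone hits
#'
#' Every recorded OH-backbone reaction independently induces an SSB with
#' probability `P_OH`. Repeat hits on a site already broken do not add
#' breaks (duplicates are merged).
#'
#' @param dna_hits hit list from [dna_hit_events()].
#' @param params a [damage_params()] (or a bare probability).
#' @param primary_id primary label attached to the breaks.
#' @return strand-break data frame with `source = "indirect"`.
#' @export
score_indirect <- function(dna_hits, params = damage_params(),
                           primary_id = 0L) {
  p_oh <- if (inherits(params, "damage_params")) params$P_OH else params
  empty <- data.frame(chromosome = integer(), strand = integer(),
                      bp = integer(), source = character(),
                      primary_id = integer())
  if (nrow(dna_hits) == 0) return(empty)
  broke <- runif(nrow(dna_hits)) < p_oh
  hit <- dna_hits[broke, , drop = FALSE]
  hit <- hit[!duplicated(hit[, c("chromosome", "strand", "bp")]), ,
             drop = FALSE]
  if (nrow(hit) == 0) return(empty)
  data.frame(chromosome = hit$chromosome, strand = hit$strand, bp = hit$bp,
             source = "indirect", primary_id = primary_id,
             row.names = NULL)
}

#' Merge strand-break lists
#'
#' Deduplicates breaks at the same (chromosome, strand, bp) within a
#' primary. When a site is broken both directly and indirectly the direct
#' label wins, since the physical stage precedes the chemical stage.
#'
#' @param ... strand-break data frames.
#' @return merged break data frame.
#' @export
merge_breaks <- function(...) {
  brk <- do.call(rbind, list(...))
  if (is.null(brk) || nrow(brk) == 0)
    return(data.frame(chromosome = integer(), strand = integer(),
                      bp = integer(), source = character(),
                      primary_id = integer()))
  ord <- order(brk$primary_id, brk$chromosome, brk$bp, brk$strand,
               brk$source)  # "direct" < "indirect"
  brk <- brk[ord, , drop = FALSE]
  dup <- duplicated(brk[, c("primary_id", "chromosome", "strand", "bp")])
  out <- brk[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}
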