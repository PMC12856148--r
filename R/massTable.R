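#' Monoisotopic residue mass table
#'
#' Masses of the 20 standard amino-acid residues (peptide-bond residues, i.e.
#' amino acid minus water) in Daltons, from the IUPAC 2021 atomic masses as
#' tabulated by the major search engines. Leucine and isoleucine are isobaric.
#'
#' @return Named numeric vector of length 20 (one-letter codes).
#' @examples
#' aaMassTable()[["G"]]
#' @export
aaMassTable <- function() {
    c(
        G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
        V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
        I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
        K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
        F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
    )
}

#' Proton and water monoisotopic masses used for fragment ions
#' @keywords internal
.PROTON <- 1.00728
.WATER <- 18.01056

#' Default biochemical category map for amino acids
#'
#' Five-class partition of the 20 standard residues used to classify a
#' substitution as conservative (within-category) or not: nonpolar/aliphatic,
#' aromatic, polar-uncharged, positively charged, negatively charged. Val/Ile,
#' Met/Leu are nonpolar and Tyr/Phe aromatic under this scheme, consistent
#' with the canonical examples of translational-error substitutions.
#'
#' @return Named character vector mapping residue to category label.
#' @examples
#' biochemCategories()[c("V", "I", "D", "K")]
#' @export
biochemCategories <- function() {
    c(
        G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
        I = "nonpolar", P = "nonpolar", M = "nonpolar",
        F = "aromatic", W = "aromatic", Y = "aromatic",
        S = "polar", T = "polar", C = "polar", N = "polar", Q = "polar",
        K = "positive", R = "positive", H = "positive",
        D = "negative", E = "negative"
    )
}

#' Mass shift of an amino-acid substitution
#'
#' Monoisotopic mass difference caused by substituting \code{from_aa} with
#' \code{to_aa} (destination minus origin). The destination may be \code{"X"},
#' the isobaric Leu/Ile ambiguity class, which uses the shared L/I mass.
#'
#' @param from_aa,to_aa Single-letter residue codes (vectorised). \code{to_aa}
#'   may be \code{"X"} for the Leu/Ile class.
#' @param table Residue mass table, as from [aaMassTable()].
#' @return Numeric vector of mass shifts in Da.
#' @examples
#' saavMassShift("D", "E") # +14.01565
#' @export
saavMassShift <- function(from_aa, to_aa, table = aaMassTable()) {
    lookup <- function(aa) {
        m <- ifelse(aa == "X", table[["L"]], unname(table[aa]))
        if (anyNA(m)) {
            stop("unknown residue(s): ",
                 paste(unique(aa[is.na(m)]), collapse = ", "))
        }
        m
    }
    lookup(to_aa) - lookup(from_aa)
}

#' Is a substitution within the same biochemical category?
#'
#' @param from_aa,to_aa Single-letter residue codes (vectorised). \code{"X"}
#'   is treated as the Leu/Ile class (nonpolar).
#' @param map Category map, as from [biochemCategories()].
#' @return Logical vector.
#' @examples
#' classifySubstitution("Y", "F") # TRUE (both aromatic)
#' @export
classifySubstitution <- function(from_aa, to_aa, map = biochemCategories()) {
    cat_of <- function(aa) {
        k <- ifelse(aa == "X", "L", aa)
        v <- unname(map[k])
        if (anyNA(v)) {
            stop("residue(s) missing from category map: ",
                 paste(unique(aa[is.na(v)]), collapse = ", "))
        }
        v
    }
    cat_of(from_aa) == cat_of(to_aa)
}

#' Theoretical SAAV mass-shift universe
#'
#' All ordered substitutions of one standard residue by another, with
#' destinations Leu/Ile collapsed into the ambiguity class \code{"X"} (one
#' entry per origin): by mass alone the two cannot be told apart. Substitutions
#' with zero mass shift (Ile/Leu interchange) are excluded, since a
#' near-zero open-search mass shift is not interpretable as a variant.
#'
#' @param table Residue mass table.
#' @return data.frame with columns \code{from_aa}, \code{to_aa},
#'   \code{delta_mass}.
#' @export
saavShiftTable <- function(table = aaMassTable()) {
    aas <- names(table)
    grid <- expand.grid(from_aa = aas, to_aa = aas,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$from_aa != grid$to_aa, ]
    # collapse I/L destinations into 'X'
    grid$to_aa[grid$to_aa %in% c("I", "L")] <- "X"
    grid <- unique(grid)
    grid$delta_mass <- saavMassShift(grid$from_aa, grid$to_aa, table)
    # drop mass-silent interchanges (I<->L)
    grid <- grid[abs(grid$delta_mass) > 1e-6, ]
    rownames(grid) <- NULL
    grid
}
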