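#' Reference population metadata for the Malaysian sampling design
#'
#' Returns the 27-population sampling frame used throughout the package as
#' the default study design: population code, name, state, region (Western
#' or Eastern Malaysia), coordinates, and sample sizes for the chloroplast
#' (`n_pop`) and STR (`n_ind`) tiers. Peninsular Malaysian populations form
#' the Western region; Sarawak and Sabah populations form the Eastern region.
#'
#' @return A `data.frame` with columns `code`, `name`, `state`, `region`,
#'   `latitude`, `longitude`, `n_pop`, `n_ind`.
#' @examples
#' pops <- shorea_populations()
#' sum(pops$n_ind)            # 1032 individuals in the STR tier
#' sum(pops$n_pop)            # 214 individuals in the chloroplast tier
#' table(pops$region)
#' @export
shorea_populations <- function() {
  data.frame(
    code = 1:27,
    name = c("Petuang", "Tembat", "Hulu Terengganu", "Gunung Basur", "Balah",
             "Gunung Stong", "Sungai Betis", "Gunung Rabong", "Belum",
             "Temenggor", "Piah", "Bintang Hijau", "Bukit Larut", "Bubu",
             "Bukit Kinta", "Bukit Tapah", "Ulu Jelai", "Fraser", "Awana",
             "Gunung Bunga Buah", "Bukit Tinggi", "Lentang", "Semangkok",
             "Berembun", "Nanga Amang", "Putai", "Rafflesia"),
    state = c("Terengganu", "Terengganu", "Terengganu", "Kelantan", "Kelantan",
              "Kelantan", "Kelantan", "Kelantan", "Perak", "Perak", "Perak",
              "Perak", "Perak", "Perak", "Perak", "Perak", "Pahang", "Pahang",
              "Pahang", "Pahang", "Pahang", "Pahang", "Selangor",
              "N. Sembilan", "Sarawak", "Sarawak", "Sabah"),
    region = c(rep("Western", 24), rep("Eastern", 3)),
    latitude = c(5.34, 5.19, 4.95, 5.51, 5.25, 5.21, 4.75, 4.83, 5.61, 5.52,
                 5.09, 4.93, 4.87, 4.66, 4.53, 4.40, 4.61, 3.70, 3.39, 3.37,
                 3.35, 3.24, 3.64, 2.83, 1.51, 1.52, 5.77),
    longitude = c(102.71, 102.60, 102.92, 101.81, 101.63, 101.95, 101.44,
                  102.14, 101.66, 101.61, 101.33, 100.88, 100.79, 100.84,
                  101.30, 101.38, 101.90, 101.73, 101.79, 101.77, 101.79,
                  102.03, 101.74, 102.05, 113.09, 114.55, 116.35),
    n_pop = c(8, 8, 6, rep(8, 24)),
    n_ind = c(16, 47, 6, 35, 19, 36, 37, 35, 32, 36, 29, 44, 75, 11, 25, 95,
              86, 45, 46, 31, 41, 10, 52, 44, 41, 29, 29),
    stringsAsFactors = FALSE
  )
}

#' Reference STR locus panel
#'
#' The 15-locus STR panel used as the default simulation target, with the
#' number of distinct alleles per locus used by the simulator's default
#' configuration.
#'
#' @return A `data.frame` with columns `locus` and `n_alleles`.
#' @examples
#' shorea_loci()
#' @export
shorea_loci <- function() {
  data.frame(
    locus = c("Spl003", "Spl529", "Spl599", "Spl600", "Spl629", "Spl667",
              "Spl676", "Spl690", "Spl763", "Spl764", "Spl834", "Spl845",
              "Spl855", "Spl858", "Spl863"),
    n_alleles = c(17, 16, 13, 12, 21, 26, 31, 19, 18, 23, 17, 28, 19, 25, 18),
    stringsAsFactors = FALSE
  )
}

# Chloroplast intergenic spacers: names, aligned lengths (bp) and the default
# number of variable sites contributed by each spacer.
.cp_spacers <- function() {
  data.frame(
    spacer = c("trnT-trnL", "trnS-trnG", "atpB-rbcL", "petG-trnP",
               "trnG-atpA", "psbM-trnD", "trnG-rps14"),
    length = c(314L, 277L, 531L, 449L, 362L, 559L, 400L),
    n_sites = c(2L, 8L, 5L, 3L, 5L, 11L, 5L),
    stringsAsFactors = FALSE
  )
}
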