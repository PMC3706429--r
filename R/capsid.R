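# Icosahedral lattice arithmetic: triangulation numbers and capsid
# subunit stoichiometry. An icosahedral shell built on lattice vectors
# (h, k) contains 60T subunits with T = h^2 + hk + k^2 (12 pentamers,
# the rest hexamers); in tailed phages one pentameric vertex is replaced
# by the dodecameric portal, displacing 5 subunits.

#' Triangulation number from lattice indices
#'
#' @param h,k Non-negative integers, not both zero.
#' @return `h^2 + h*k + k^2`.
#' @examples
#' tNumber(3, 1) # 13
#' @export
tNumber <- function(h, k) {
  h <- as.integer(h); k <- as.integer(k)
  if (h < 0L || k < 0L) stop("h and k must be non-negative")
  if (h == 0L && k == 0L) stop("(h, k) = (0, 0) is not a lattice")
  h^2L + h * k + k^2L
}

#' Enumerate valid triangulation numbers
#'
#' @param max_T Largest T to enumerate.
#' @return `data.frame` with `T`, `h`, `k` (canonical representative with
#'   `h >= k`), sorted by `T`.
#' @export
enumerateT <- function(max_T) {
  if (max_T < 1L) stop("max_T must be >= 1")
  hk_max <- as.integer(ceiling(sqrt(max_T)))
  grid <- expand.grid(h = 0:hk_max, k = 0:hk_max)
  grid <- grid[grid$h >= grid$k & !(grid$h == 0 & grid$k == 0), ]
  grid$T <- grid$h^2 + grid$h * grid$k + grid$k^2
  grid <- grid[grid$T <= max_T, c("T", "h", "k")]
  grid <- grid[!duplicated(grid$T), ]
  grid <- grid[order(grid$T), ]
  rownames(grid) <- NULL
  grid
}

valid_T <- function(T) T %in% enumerateT(max(1L, as.integer(T)))$T

#' Capsid subunit copy number from the triangulation number
#'
#' `60 * T` subunits per shell; 5 fewer per virion when the portal
#' replaces one pentameric vertex.
#'
#' @param T A valid triangulation number.
#' @param portal_present Is one vertex occupied by the portal?
#' @return Integer copy number.
#' @examples
#' subunitCount(13, portal_present = TRUE) # 775
#' @export
subunitCount <- function(T, portal_present = FALSE) {
  T <- as.integer(T)
  if (!valid_T(T)) stop(T, " is not a valid triangulation number")
  60L * T - if (portal_present) 5L else 0L
}

#' Infer the triangulation number from a subunit copy number
#'
#' @param copies Subunit copies per virion (>= 55).
#' @param portal_present Was one pentameric vertex replaced by a portal?
#' @return The triangulation number.
#' @examples
#' inferT(775, portal_present = TRUE) # 13
#' @export
inferT <- function(copies, portal_present = FALSE) {
  copies <- as.integer(copies)
  if (copies < 55L) stop("copies must be >= 55")
  raw <- copies + if (portal_present) 5L else 0L
  if (raw %% 60L != 0L) {
    lo <- (raw %/% 60L) * 60L
    stop("copy number does not fit 60T", if (portal_present) " - 5" else "",
         "; nearest valid counts are ",
         lo - if (portal_present) 5L else 0L, " and ",
         lo + 60L - if (portal_present) 5L else 0L)
  }
  T <- raw %/% 60L
  if (!valid_T(T)) stop("T = ", T, " is not expressible as h^2 + hk + k^2")
  T
}

#' Full capsid geometry report
#'
#' @param T Triangulation number.
#' @param portal_present Portal at one vertex?
#' @return A [CapsidGeometry-class]; both chiral (h, k) classes are
#'   reported via [capsidReport()] since T alone does not fix handedness.
#' @export
capsidGeometry <- function(T, portal_present = TRUE) {
  T <- as.integer(T)
  rep <- enumerateT(T)
  rep <- rep[rep$T == T, ]
  if (!nrow(rep)) stop(T, " is not a valid triangulation number")
  new("CapsidGeometry",
    h = as.integer(rep$h[1]), k = as.integer(rep$k[1]), T = T,
    subunits_total = 60L * T,
    subunits_virion = subunitCount(T, portal_present),
    portal_present = portal_present
  )
}

#' Capsid report as a plain list (JSON-ready)
#'
#' @param T Triangulation number.
#' @param portal_present Portal at one vertex?
#' @return List with `T`, `hk_candidates` (both chiral classes where they
#'   differ), `subunits_total`, `subunits_virion`, `pentamers`.
#' @export
capsidReport <- function(T, portal_present = TRUE) {
  geom <- capsidGeometry(T, portal_present)
  hk <- if (geom@h != geom@k && geom@k != 0L) {
    list(c(h = geom@h, k = geom@k), c(h = geom@k, k = geom@h))
  } else {
    list(c(h = geom@h, k = geom@k))
  }
  list(
    T = geom@T,
    hk_candidates = hk,
    subunits_total = geom@subunits_total,
    subunits_virion = geom@subunits_virion,
    pentamers = if (portal_present) 11L else 12L,
    portal_present = portal_present
  )
}
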