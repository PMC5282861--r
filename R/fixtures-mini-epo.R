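#' @title Mini-EPO fixture
#' @description A deterministic miniature of the ectopic-pregnancy knowledge
#'   base reconstructed from published content: the evaluated sign inventory,
#'   the type taxonomy by implantation site, the anatomy and technical
#'   hierarchies the ring-of-fire sign touches, the defined sign categories,
#'   and the ring-of-fire relations and reference annotation. It does not
#'   attempt to recreate the full production ontology (about 1,400 classes);
#'   counts asserted in tests are the fixture manifest's, never the
#'   production ontology's.
#' @name mini-epo
NULL

#' Deterministic fixture identifier for a label
#'
#' Fixture identifiers follow the production pattern `epo:OPPIO_` + 7
#' characters; apart from the two fixed roots they are stable hashes of the
#' English preferred label, so cross-module tests can refer to concepts
#' symbolically.
#'
#' @param label English preferred label.
#' @return A concept identifier string.
#' @export
mini_epo_id <- function(label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 268435456  # 16^7
  paste0("epo:OPPIO_", sprintf("%07x", h))
}

SIGN_ROOT_ID <- "epo:OPPIO_0000189"
DISORDER_ROOT_ID <- "epo:OPPIO_c000016"

# the 24 evaluated sign labels as printed in the agreement table
table4_sign_labels <- function() c(
  "Endometrial trilaminar pattern",
  "Adnexal mass distinct from ovary",
  "Embryo visible outside the uterine cavity",
  "Gestational sac outside the uterine cavity",
  "Adnexal mass adjacent to ovary",
  "Gestational sac or trophoblast in a myometrial defect in previous caesarean section scar pregnancy site",
  "Adnexal mass and corpus luteum at the same side",
  "Adnexal rounded hyperechoic mass",
  "Ring of fire sign",
  "Yolk sac visible outside the uterine cavity",
  "Adnexal mass as gestational sac with yolk sac",
  "Caesarean section scar pregnancy peritrophoblastic blood flow",
  "Intact endometrial midline echo",
  "Tubal ring sign",
  "Tubal ring without central identifying feature",
  "Trophoblast visible outside the uterine cavity",
  "Anterior distortion of uterus serosa",
  "Smaller trophoblastic border distance to the anterior uterine serosa",
  "Ectopic pregnancy wall more echogenic than corpus luteum wall",
  "Fluid collection located centrally within the uterine cavity",
  "Non intact endometrial midline echo",
  "Gestational sac or trophoblast located at the level of internal cervical os",
  "Gestational sac inside anterior myometrium and uterine cavity",
  "Gestational sac located eccentricaly from uterine cavity")

#' Build the mini-EPO knowledge base
#'
#' Deterministic; passes [validate_kb()] with zero issues. Contains the 24
#' evaluated signs plus the interstitial line sign; the type taxonomy with
#' tubal (and its ampullary/isthmic/fimbrial subtypes), interstitial,
#' cervical and cesarean-section-scar pregnancy, declared pairwise disjoint;
#' anatomy including the uterus (FMAID 17558), the uterine tube zones and
#' early gestational structures; the technical hierarchies (vaginal route,
#' color Doppler mode with its 2D child, adnexal area view, ...); the four
#' defined sign categories; the full ring-of-fire relation set; and the
#' ring-of-fire reference annotation (PMID 18936028).
#'
#' @return A validated `epo_kb`.
#' @export
build_mini_epo <- function() {
  concepts <- list()
  ids <- new.env(parent = emptyenv())
  add <- function(label, id = mini_epo_id(label), alt = NULL, fr = NULL,
                  def = NULL, fma = NULL, pmids = character(0),
                  paths = character(0)) {
    pref <- c(en = label)
    if (!is.null(fr)) pref <- c(pref, fr = fr)
    if (!is.null(get0(label, envir = ids)))
      epokb_stop(paste0("fixture label collision: ", label), "epokb_internal")
    assign(label, id, envir = ids)
    concepts[[length(concepts) + 1L]] <<- epo_concept(
      id, pref_labels = pref,
      alt_labels = if (is.null(alt)) NULL else c(en = alt),
      definitions = if (is.null(def)) NULL else c(en = def),
      fma_id = fma, pmids = pmids, image_paths = paths)
    id
  }
  id_of <- function(label) get(label, envir = ids)

  # roots
  add("imaging sign", id = SIGN_ROOT_ID, alt = "ultrasound sign",
      def = "A visually recognizable feature of an ultrasound image.")
  add("ectopic pregnancy", id = DISORDER_ROOT_ID,
      def = "Implantation of a gestational sac outside the endometrial cavity.")
  add("anatomical structure")
  add("examination route")
  add("examination mode")
  add("echographic view")

  # types of ectopic pregnancy by implantation site
  add("tubal pregnancy",
      def = "Ectopic pregnancy implanted in the fallopian tube.")
  add("interstitial pregnancy",
      def = "Ectopic pregnancy implanted in the interstitial portion of the tube.")
  add("cervical pregnancy",
      def = "Ectopic pregnancy implanted in the cervical canal.")
  add("cesarean section scar pregnancy", alt = "c-section scar pregnancy",
      def = "Ectopic pregnancy implanted in a previous cesarean section scar.")
  add("ampullary pregnancy")
  add("isthmic pregnancy")
  add("fimbrial pregnancy")

  # anatomy
  add("uterus", fma = "17558")
  add("uterine tube", alt = "fallopian tube")
  add("zone of uterine tube")
  add("ampulla")
  add("tubal isthmus")
  add("fimbrial portion", alt = "frimbrial portion")
  add("ovary")
  add("corpus luteum")
  add("gestational sac")
  add("trophoblast")

  # technical elements
  add("vaginal route", alt = "transvaginal route")
  add("abdominal route")
  add("2D mode")
  add("color Doppler mode")
  add("color Doppler mode (2D)")
  add("adnexal area view")
  add("longitudinal view of the uterus")

  # primitive signs: the 24 evaluated labels (stored lowercase, with the
  # printed sentence-case form as an alternative label) plus the
  # interstitial line sign
  sign_defs <- c(
    "endometrial trilaminar pattern" = "Three-layered appearance of the endometrium.",
    "adnexal mass distinct from ovary" = "Adnexal mass seen separately from the ipsilateral ovary.",
    "embryo visible outside the uterine cavity" = "An embryonic pole outside the endometrial cavity.",
    "gestational sac outside the uterine cavity" = "A gestational sac outside the endometrial cavity.",
    "adnexal mass adjacent to ovary" = "Adnexal mass abutting the ipsilateral ovary.",
    "gestational sac or trophoblast in a myometrial defect in previous caesarean section scar pregnancy site" =
      "Sac or trophoblast within the myometrial defect of a cesarean scar.",
    "adnexal mass and corpus luteum at the same side" = "Adnexal mass ipsilateral to the corpus luteum.",
    "adnexal rounded hyperechoic mass" = "Rounded echogenic mass in the adnexa.",
    "ring of fire sign" = "Peritrophoblastic low-resistance flow forming a vascular ring around an adnexal mass on color Doppler.",
    "yolk sac visible outside the uterine cavity" = "A yolk sac outside the endometrial cavity.",
    "adnexal mass as gestational sac with yolk sac" = "Adnexal sac-like mass containing a yolk sac.",
    "caesarean section scar pregnancy peritrophoblastic blood flow" = "Peritrophoblastic flow at a cesarean scar implantation site.",
    "intact endometrial midline echo" = "Uninterrupted endometrial midline echo.",
    "tubal ring sign" = "Echogenic ring surrounding an extrauterine gestational sac.",
    "tubal ring without central identifying feature" = "Tubal ring lacking yolk sac or embryo.",
    "trophoblast visible outside the uterine cavity" = "Trophoblastic tissue outside the endometrial cavity.",
    "anterior distortion of uterus serosa" = "Bulging of the anterior uterine serosal contour.",
    "smaller trophoblastic border distance to the anterior uterine serosa" = "Thin myometrium between trophoblast and anterior serosa.",
    "ectopic pregnancy wall more echogenic than corpus luteum wall" = "Ectopic sac wall brighter than the corpus luteum wall.",
    "fluid collection located centrally within the uterine cavity" = "Central intracavitary fluid (pseudosac).",
    "non intact endometrial midline echo" = "Interrupted endometrial midline echo.",
    "gestational sac or trophoblast located at the level of internal cervical os" = "Implantation at the internal cervical os.",
    "gestational sac inside anterior myometrium and uterine cavity" = "Sac bridging the anterior myometrium and the cavity.",
    "gestational sac located eccentricaly from uterine cavity" = "Sac eccentric to the endometrial cavity.",
    "interstitial line sign" = "Echogenic line from the endometrium to an interstitial sac.")
  printed <- c(table4_sign_labels(), "Interstitial line sign")
  for (i in seq_along(sign_defs)) {
    lab <- names(sign_defs)[i]
    extra_alt <- if (!identical(printed[i], lab)) printed[i] else NULL
    if (lab == "ring of fire sign") {
      add(lab, alt = extra_alt, fr = "signe de l'anneau de feu",
          def = sign_defs[[i]], pmids = "18936028",
          paths = "images/ring_of_fire.png")
    } else {
      add(lab, alt = extra_alt, def = sign_defs[[i]])
    }
  }

  # defined sign categories (necessary-and-sufficient definitions)
  add("color Doppler sign",
      def = "An imaging sign requiring the color Doppler mode.")
  add("2D ultrasound sign",
      def = "An imaging sign requiring the 2D mode.")
  add("tubal pregnancy sign",
      def = "An imaging sign suggesting tubal pregnancy.")
  add("c-section scar pregnancy sign",
      def = "An imaging sign suggesting cesarean section scar pregnancy.")

  sub <- function(child, parent) ax_subclass(id_of(child), id_of(parent))
  res <- function(child, property, filler)
    ax_restriction(id_of(child), property, id_of(filler))

  axioms <- c(
    lapply(c("tubal pregnancy", "interstitial pregnancy", "cervical pregnancy",
             "cesarean section scar pregnancy"),
           sub, parent = "ectopic pregnancy"),
    lapply(c("ampullary pregnancy", "isthmic pregnancy", "fimbrial pregnancy"),
           sub, parent = "tubal pregnancy"),
    lapply(c("uterus", "uterine tube", "ovary", "corpus luteum",
             "gestational sac", "trophoblast"),
           sub, parent = "anatomical structure"),
    list(sub("zone of uterine tube", "uterine tube"),
         sub("ampulla", "zone of uterine tube"),
         sub("tubal isthmus", "zone of uterine tube"),
         sub("fimbrial portion", "zone of uterine tube"),
         sub("vaginal route", "examination route"),
         sub("abdominal route", "examination route"),
         sub("2D mode", "examination mode"),
         sub("color Doppler mode", "examination mode"),
         sub("color Doppler mode (2D)", "color Doppler mode"),
         sub("color Doppler mode (2D)", "2D mode"),
         sub("adnexal area view", "echographic view"),
         sub("longitudinal view of the uterus", "echographic view")),
    lapply(names(sign_defs), sub, parent = "imaging sign"),
    # ring-of-fire relation set
    list(res("ring of fire sign", "suggests", "tubal pregnancy"),
         res("ring of fire sign", "hasLocation", "ampulla"),
         res("ring of fire sign", "hasLocation", "tubal isthmus"),
         res("ring of fire sign", "hasLocation", "fimbrial portion"),
         res("ring of fire sign", "requiresRoute", "vaginal route"),
         res("ring of fire sign", "requiresMode", "color Doppler mode (2D)"),
         res("ring of fire sign", "requiresView", "adnexal area view"),
         # other asserted sign relations
         res("tubal ring sign", "suggests", "tubal pregnancy"),
         res("tubal ring sign", "hasLocation", "uterine tube"),
         res("tubal ring sign", "requiresMode", "2D mode"),
         res("tubal ring sign", "requiresView", "adnexal area view"),
         res("interstitial line sign", "suggests", "interstitial pregnancy"),
         res("interstitial line sign", "hasLocation", "uterus"),
         res("caesarean section scar pregnancy peritrophoblastic blood flow",
             "suggests", "cesarean section scar pregnancy"),
         res("caesarean section scar pregnancy peritrophoblastic blood flow",
             "requiresMode", "color Doppler mode"),
         res(paste("gestational sac or trophoblast in a myometrial defect in",
                   "previous caesarean section scar pregnancy site"),
             "suggests", "cesarean section scar pregnancy"),
         res("gestational sac or trophoblast located at the level of internal cervical os",
             "suggests", "cervical pregnancy")),
    # defined classes
    list(
      ax_defined(id_of("color Doppler sign"), SIGN_ROOT_ID,
                 list(list(property = "requiresMode",
                           filler = id_of("color Doppler mode")))),
      ax_defined(id_of("2D ultrasound sign"), SIGN_ROOT_ID,
                 list(list(property = "requiresMode",
                           filler = id_of("2D mode")))),
      ax_defined(id_of("tubal pregnancy sign"), SIGN_ROOT_ID,
                 list(list(property = "suggests",
                           filler = id_of("tubal pregnancy")))),
      ax_defined(id_of("c-section scar pregnancy sign"), SIGN_ROOT_ID,
                 list(list(property = "suggests",
                           filler = id_of("cesarean section scar pregnancy")))),
      ax_disjoint(c(id_of("tubal pregnancy"), id_of("interstitial pregnancy"),
                    id_of("cervical pregnancy"),
                    id_of("cesarean section scar pregnancy"))))
  )

  epo_kb(concepts, axioms,
         sign_root = SIGN_ROOT_ID,
         disorder_root = DISORDER_ROOT_ID,
         anatomy_root = id_of("anatomical structure"),
         technical_roots = c(id_of("examination route"),
                             id_of("examination mode"),
                             id_of("echographic view")))
}

#' Mini-EPO manifest
#'
#' The expected inventory of the fixture, kept separately from the builder so
#' tests can detect silent drift: counts, key identifiers, the expected
#' defined-class memberships and the per-type asserted sign map.
#'
#' @return A list of expectations (see source for fields).
#' @export
mini_epo_manifest <- function() {
  rof <- mini_epo_id("ring of fire sign")
  list(
    n_concepts = 59L,                     # 6 roots + 7 types + 10 anatomy +
                                          # 7 technical + 25 signs + 4 defined
    n_signs = 30L,                        # primitive + defined + sign root
    n_primitive_signs = 25L,
    sign_root = SIGN_ROOT_ID,
    disorder_root = DISORDER_ROOT_ID,
    top_disorders = sort_c(vapply(
      c("tubal pregnancy", "interstitial pregnancy", "cervical pregnancy",
        "cesarean section scar pregnancy"), mini_epo_id, character(1),
      USE.NAMES = FALSE)),
    ring_of_fire = rof,
    n_pmid_annotations = 1L,
    n_image_annotations = 1L,
    pmid = "18936028",
    axiom_counts = c(subclass_of = 50L, subclass_of_restriction = 17L,
                     equivalent_to_definition = 4L, disjoint = 1L),
    defined_memberships = list(
      "color Doppler sign" = sort_c(c(
        "ring of fire sign",
        "caesarean section scar pregnancy peritrophoblastic blood flow")),
      "2D ultrasound sign" = sort_c(c("ring of fire sign", "tubal ring sign")),
      "tubal pregnancy sign" = sort_c(c("ring of fire sign", "tubal ring sign")),
      "c-section scar pregnancy sign" = sort_c(c(
        "caesarean section scar pregnancy peritrophoblastic blood flow",
        paste("gestational sac or trophoblast in a myometrial defect in",
              "previous caesarean section scar pregnancy site")))),
    signs_by_type = list(
      "tubal pregnancy" = sort_c(c("ring of fire sign", "tubal ring sign")),
      "interstitial pregnancy" = "interstitial line sign",
      "cervical pregnancy" =
        "gestational sac or trophoblast located at the level of internal cervical os",
      "cesarean section scar pregnancy" = sort_c(c(
        "caesarean section scar pregnancy peritrophoblastic blood flow",
        paste("gestational sac or trophoblast in a myometrial defect in",
              "previous caesarean section scar pregnancy site"))))
  )
}
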