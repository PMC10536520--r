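test_that("fixture provider replays ground truth, with optional bias", {
  sp <- clean_spec()
  fr <- render_frame(sp, 0)
  prov <- fixture_landmark_provider(list(fr$landmarks), frame_index = 0L)
  lm <- provide_landmarks(prov, frame_index = 0L, image_size = dim(fr$image))
  expect_equal(lm$points, fr$landmarks, ignore_attr = TRUE)
  expect_true(lm$valid)
  expect_identical(lm$source, "fixture")
  # +3 px downward bias on the lower-lid landmarks only
  provb <- fixture_landmark_provider(list(fr$landmarks), frame_index = 0L,
                                     bias = list(indices = 41:42, offset = c(0, 3)))
  lmb <- provide_landmarks(provb, frame_index = 0L)
  expect_equal(lmb$points[41:42, 2], fr$landmarks[41:42, 2] + 3, ignore_attr = TRUE)
  expect_equal(lmb$points[-(41:42), ], fr$landmarks[-(41:42), ], ignore_attr = TRUE)
  # unknown frame -> absent
  expect_null(provide_landmarks(prov, frame_index = 99L))
})

test_that("an external provider that finds no face yields absent, and a missing provider errors", {
  prov <- external_landmark_provider(function(img) NULL)
  expect_null(provide_landmarks(prov, frame = matrix(0, 50, 50)))
  expect_error(provide_landmarks(NULL, frame = matrix(0, 5, 5)), "provider")
  expect_error(provide_landmarks(list(), frame = matrix(0, 5, 5)), "provider")
})

test_that("eye hexagons use annotation indices 37-42 / 43-48 in order", {
  sp <- clean_spec()
  fr <- render_frame(sp, 0)
  lm <- landmark_set(fr$landmarks, image_size = dim(fr$image))
  hx <- extract_eye_hexagons(lm)
  expect_equal(hx$right$vertices, fr$landmarks[37:42, ], ignore_attr = TRUE)
  expect_equal(hx$left$vertices, fr$landmarks[43:48, ], ignore_attr = TRUE)
  expect_false(hx$right$degenerate)
  expect_false(hx$left$degenerate)
})

test_that("coincident vertices mark a hexagon degenerate", {
  v <- cbind(x = c(10, 20, 30, 40, 30, 20), y = c(25, 20, 20, 25, 30, 30))
  expect_false(make_hexagon(v)$degenerate)
  v2 <- v; v2[2, ] <- v2[1, ] + c(0.5, 0.5)  # within 1 px
  expect_true(make_hexagon(v2)$degenerate)
})

test_that("eye localization sanity check flags nares-like and implausible layouts", {
  sp <- clean_spec()
  fr <- render_frame(sp, 0)
  lm <- landmark_set(fr$landmarks, image_size = dim(fr$image))
  box <- landmark_face_box(lm)
  hx <- extract_eye_hexagons(lm)
  expect_true(validate_eye_localization(hx, box)$valid)

  # hexagons translated onto the nares (nose-base landmarks 32-36)
  nares_y <- mean(fr$landmarks[32:36, 2])
  shift <- function(hex, dx, dy) {
    hex$vertices <- sweep(hex$vertices, 2, c(dx, dy), "+"); hex
  }
  dy <- nares_y - mean(hx$right$vertices[, 2])
  hx_nares <- list(right = shift(hx$right, 20, dy), left = shift(hx$left, -20, dy))
  v <- validate_eye_localization(hx_nares, box)
  expect_false(v$valid)
  expect_identical(v$reason, "below mid-face")

  # inter-ocular distance 5% of the face width
  w <- box["x1"] - box["x0"]
  cr <- colMeans(hx$right$vertices); cl <- colMeans(hx$left$vertices)
  mid <- (cr + cl) / 2
  squeeze <- function(hex, target) {
    hex$vertices <- sweep(hex$vertices, 2, colMeans(hex$vertices), "-")
    hex$vertices <- sweep(hex$vertices, 2, target, "+"); hex
  }
  hx_close <- list(right = squeeze(hx$right, mid - c(0.025 * w, 0)),
                   left = squeeze(hx$left, mid + c(0.025 * w, 0)))
  expect_false(validate_eye_localization(hx_close, box)$valid)

  # strongly tilted inter-ocular line
  hx_tilt <- list(right = shift(hx$right, 0, 40), left = shift(hx$left, 0, -40))
  vt <- validate_eye_localization(hx_tilt, box)
  expect_false(vt$valid)
  expect_identical(vt$reason, "tilted inter-ocular line")
})

test_that("ground-truth interfaces lie inside the hexagon bounding box (ROI containment)", {
  for (seed in 1:3) {
    sp <- clean_spec(seed = seed, noise_sigma = 0)
    fr <- render_frame(sp, 0)
    lm <- landmark_set(fr$landmarks, image_size = dim(fr$image))
    hx <- extract_eye_hexagons(lm)
    for (side in c("right", "left")) {
      tr <- fr$truth[fr$truth$side == side, ]
      v <- hx[[side]]$vertices
      for (y in c(tr$upper_lid_y, tr$lower_lid_y, tr$iris_bottom_y)) {
        expect_gte(y, min(v[, 2]) - 2)
        expect_lte(y, max(v[, 2]) + 2)
      }
    }
  }
})

test_that("landmark CSV round-trips frame indices, timestamps and points", {
  pts <- lapply(1:3, function(i) matrix(runif(136, 1, 100), 68, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(pts, frame_index = c(0L, 2L, 4L),
                      timestamps = c(0, 1, 2) / 15, path = path)
  back <- read_landmarks_csv(path)
  expect_equal(back$frame_index, c(0L, 2L, 4L))
  expect_equal(back$timestamps, c(0, 1, 2) / 15)
  expect_equal(back$landmarks[[2]], pts[[2]], tolerance = 1e-12, ignore_attr = TRUE)
})
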