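solid <- function(value, h = 320, w = 320) {
  annotated_image(array(value, dim = c(h, w, 3)))
}

test_that("letterbox resize scales by the limiting axis and pads with gray", {
  img <- matrix(0.2, 320, 320)
  lb <- letterbox_resize(img, size = 640)
  expect_identical(dim(lb$image), c(640L, 640L))
  expect_equal(lb$scale, 2)
  # non-square: 160 x 320 scales by 2 -> 320 x 640, rows 321+ are pad
  lb2 <- letterbox_resize(matrix(0.2, 160, 320), size = 640)
  expect_equal(lb2$scale, 2)
  expect_equal(lb2$image[500, 10], 114 / 255)
  expect_equal(lb2$image[100, 10], 0.2)
})

test_that("box remap under scale-then-translate and clipping match the oracles", {
  b <- boxes_df(0L, 10, 10, 50, 50)
  # scale 2, offset (0, 0): (10,10,50,50) -> (20,20,100,100)
  r <- polypstab:::remap_boxes(b, 2, 0, 0)
  expect_equal(unlist(r[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 20, y_min = 20, x_max = 100, y_max = 100))
  # crop at x = 60 clips to (20,20,60,100)
  cl <- clip_boxes(r, x_lim = c(0, 60), y_lim = c(0, 640))
  expect_equal(unlist(cl[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 20, y_min = 20, x_max = 60, y_max = 100))
  # fully outside the clip region -> dropped
  expect_identical(nrow(clip_boxes(r, c(100, 640), c(0, 640))), 0L)
})

test_that("mosaic of four identical solid images is solid with no boxes", {
  out <- augment_mosaic(rep(list(solid(0.3)), 4), size = 640,
                        center = c(320, 320))
  expect_identical(dim(out$image), c(640L, 640L, 3L))
  expect_equal(range(out$image), c(0.3, 0.3))
  expect_identical(nrow(out$boxes), 0L)
})

test_that("mosaic remaps, clips and conserves boxes per tile", {
  mk <- function(...) {
    a <- solid(0.5)
    a$boxes <- boxes_df(...)
    a
  }
  # all inputs 320x320 -> scale 2; tile offsets at center (320,320) are
  # (-320,-320), (320,-320), (-320,320), (320,320)
  imgs <- list(mk(0L, 200, 200, 300, 300),   # top-left
               mk(0L, 10, 200, 50, 300),     # top-right
               mk(0L, 200, 10, 300, 50),     # bottom-left
               mk(0L, 10, 10, 50, 50))       # bottom-right
  out <- augment_mosaic(imgs, size = 640, center = c(320, 320))
  b <- out$boxes
  expect_identical(nrow(b), 4L)
  expect_equal(b$x_min, c(80, 340, 80, 340))
  expect_equal(b$y_min, c(80, 80, 340, 340))
  expect_equal(b$x_max, c(280, 420, 280, 420))
  expect_equal(b$y_max, c(280, 280, 420, 420))
  expect_true(all(b$x_min < b$x_max & b$y_min < b$y_max))
  expect_true(all(b$x_min >= 0 & b$y_min >= 0 & b$x_max <= 640 & b$y_max <= 640))
})

test_that("boxes whose tile region is cropped away are clipped or dropped, never duplicated", {
  pad <- list(solid(0.5), solid(0.5), solid(0.5))
  a <- solid(0.5)
  a$boxes <- boxes_df(0L, 300, 300, 319, 319)  # near bottom-right of input
  # top-left tile, center (100, 100): offset (-540, -540); the box maps to
  # (600,600,638,638) - 540 = (60,60,98,98), fully inside the quadrant
  out <- augment_mosaic(c(list(a), pad), size = 640, center = c(100, 100))
  expect_identical(nrow(out$boxes), 1L)
  expect_equal(unlist(out$boxes[1, c("x_min", "x_max")]),
               c(x_min = 60, x_max = 98))
  # center (40, 40): offset (-600, -600); the box straddles the canvas
  # origin and is clipped to (0,0,38,38)
  b <- solid(0.5)
  b$boxes <- boxes_df(0L, 290, 290, 319, 319)
  out2 <- augment_mosaic(c(list(b), pad), size = 640, center = c(40, 40))
  expect_identical(nrow(out2$boxes), 1L)
  expect_equal(unlist(out2$boxes[1, c("x_min", "x_max")]),
               c(x_min = 0, x_max = 38))
  # a box entirely outside the visible tile window disappears
  cc <- solid(0.5)
  cc$boxes <- boxes_df(0L, 10, 10, 50, 50)
  out3 <- augment_mosaic(c(list(cc), pad), size = 640, center = c(40, 40))
  expect_identical(nrow(out3$boxes), 0L)
})

test_that("mosaic is reproducible for a fixed seed and rejects wrong arity", {
  imgs <- rep(list(solid(0.4, 200, 300)), 4)
  a <- augment_mosaic(imgs, seed = 77)
  b <- augment_mosaic(imgs, seed = 77)
  expect_identical(a, b)
  expect_error(augment_mosaic(imgs[1:3]), "exactly four")
  expect_error(augment_mosaic(imgs, center = c(0, 320)), "strictly inside")
})

test_that("self-mixup with transforms disabled is the identity on pixels", {
  a <- solid(0.6, 64, 64)
  a$boxes <- boxes_df(0L, 5, 5, 20, 20)
  out <- augment_mixup(a, a, jitter = 0, shift = 0, flip_prob = 0)
  expect_equal(out$image, a$image)
  expect_identical(nrow(out$boxes), 2L)  # union keeps both label sets
})

test_that("1:1 mixing averages pixel pairs exactly", {
  a <- annotated_image(matrix(100 / 255, 8, 8))
  b <- annotated_image(matrix(50 / 255, 8, 8))
  out <- augment_mixup(a, b, jitter = 0, shift = 0, flip_prob = 0)
  expect_equal(out$image, matrix(75 / 255, 8, 8))
  # commutative with transforms disabled
  expect_equal(out$image,
               augment_mixup(b, a, jitter = 0, shift = 0, flip_prob = 0)$image)
})

test_that("horizontal flip reflects box x-coordinates as x' = W - x", {
  b <- annotated_image(matrix(0.1, 480, 640),
                       boxes_df(0L, 10, 100, 50, 200))
  a <- annotated_image(matrix(0.9, 480, 640))
  out <- augment_mixup(a, b, jitter = 0, shift = 0, flip_prob = 1)
  expect_equal(unlist(out$boxes[1, c("x_min", "x_max")]),
               c(x_min = 590, x_max = 630))
  expect_equal(unlist(out$boxes[1, c("y_min", "y_max")]), c(y_min = 100, y_max = 200))
})

test_that("mixup rejects images of different sizes", {
  expect_error(augment_mixup(solid(0.5, 64, 64), solid(0.5, 64, 96)),
               "identical dimensions")
})

test_that("seeded mixup is byte-identical across calls", {
  a <- solid(0.3, 100, 100); a$boxes <- boxes_df(0L, 10, 10, 40, 40)
  b <- solid(0.7, 100, 100); b$boxes <- boxes_df(0L, 50, 50, 90, 90)
  expect_identical(augment_mixup(a, b, seed = 5), augment_mixup(a, b, seed = 5))
})
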