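"""Generate frozen colorimetry oracle fixtures with scikit-image.

Run once from the repository root:

    python tools/make_oracles.py

Writes tests/testthat/oracle_colour.csv: 100 seeded random xyY vectors,
their XYZ, the scikit-image CIE Lab (D65 2-degree white, Y-normalised),
and LCh derived from that Lab.  Also 24 RGB rows through skimage's sRGB
-> XYZ path.  The R test suite compares the package implementation
against these frozen values; it never re-runs this script.
"""
import numpy as np
from skimage import color

rng = np.random.default_rng(20160329)

# D65 2-degree observer white used by skimage's xyz2lab default
WHITE = np.array([0.95047, 1.0, 1.08883])

n = 100
x = rng.uniform(0.05, 0.6, n)
y = rng.uniform(0.05, 0.6, n)
keep = x + y <= 0.95
x, y = x[keep], y[keep]
while x.size < n:
    xx = rng.uniform(0.05, 0.6, n)
    yy = rng.uniform(0.05, 0.6, n)
    k = xx + yy <= 0.95
    x = np.concatenate([x, xx[k]])[:n]
    y = np.concatenate([y, yy[k]])[:n]
Y = rng.uniform(1.0, 100.0, n)

X = x * Y / y
Z = (1.0 - x - y) * Y / y
xyz = np.stack([X, Y, Z], axis=1)

lab = color.xyz2lab(xyz.reshape(1, n, 3) / 100.0).reshape(n, 3)
L, a, b = lab.T
C = np.hypot(a, b)
h = np.degrees(np.arctan2(b, a)) % 360.0

hdr = "x,y,Y,X,Z,L,a,b,C,h"
rows = np.stack([x, y, Y, X, Z, L, a, b, C, h], axis=1)
np.savetxt("tests/testthat/oracle_colour.csv", rows, delimiter=",",
           header=hdr, comments="", fmt="%.12g")

# sRGB -> XYZ oracle (matrix + transfer function), Y scale 0-1 in skimage
rgb8 = rng.integers(0, 256, size=(24, 3))
rgb8[0] = [255, 255, 255]
rgb8[1] = [0, 0, 0]
rgb8[2] = [255, 0, 0]
xyz_rgb = color.rgb2xyz(rgb8.reshape(1, 24, 3) / 255.0).reshape(24, 3) * 100.0
rows2 = np.concatenate([rgb8, xyz_rgb], axis=1)
np.savetxt("tests/testthat/oracle_srgb.csv", rows2, delimiter=",",
           header="r,g,b,X,Y,Z", comments="", fmt="%.12g")

# report the matrix skimage uses, to confirm the primaries-derived matrix
print(color.rgb2xyz(np.eye(3).reshape(1, 3, 3)).reshape(3, 3).T)
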