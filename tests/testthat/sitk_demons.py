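"""Reference demons registration used as an independent oracle in tests.

Reads fixed.txt / moving.txt (whitespace-separated matrices) from the
directory given as argv[1], runs a diffeomorphic demons registration, and
writes the displacement field as disp_row.txt / disp_col.txt (pixels,
pull-back convention: out(p) = moving(p + d(p))).
"""
import sys

import numpy as np
import SimpleITK as sitk

d = sys.argv[1]
fixed = np.loadtxt(f"{d}/fixed.txt")
moving = np.loadtxt(f"{d}/moving.txt")

f_img = sitk.GetImageFromArray(fixed.astype(np.float64))
m_img = sitk.GetImageFromArray(moving.astype(np.float64))

reg = sitk.DiffeomorphicDemonsRegistrationFilter()
reg.SetNumberOfIterations(100)
reg.SetStandardDeviations(2.0)
disp = reg.Execute(f_img, m_img)

arr = sitk.GetArrayFromImage(disp)  # (rows, cols, [vx, vy])
np.savetxt(f"{d}/disp_row.txt", arr[:, :, 1])
np.savetxt(f"{d}/disp_col.txt", arr[:, :, 0])
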