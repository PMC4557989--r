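# SYNTHETIC chart reference values (non-certified).
# In-gamut CIELAB (D50) coordinates spanning a neutral ramp, primaries,
# skin/tissue tones and mixed hues, laid out 6 columns x 5 rows.
# These are NOT the certified values of any commercial chart vendor.
patch_id,L,a,b
A1,95.82,-0.13,0.48
A2,80.58,-0.14,0.5
A3,65.87,0,0
A4,51.2,-0.15,0.55
A5,36.15,0,0
A6,21.7,0,0
B1,41.93,49.97,25.87
B2,55.07,-37.26,31.74
B3,29.6,20.48,-50.67
B4,81.18,0.82,77.09
B5,51.32,46.93,-14.68
B6,50.72,-23.32,-24.02
C1,38.22,12.77,13.97
C2,65.92,14.96,17.27
C3,72.58,21.47,19.28
C4,51.51,19.15,16.25
C5,77.55,16.66,17.55
C6,41.15,24.96,17.35
D1,50.35,-2.13,-21.94
D2,43.08,-14.13,20.3
D3,55.44,10.18,-25.39
D4,70.83,-30.76,1.11
D5,61.72,30.69,56.71
D6,40.57,12.45,-42.56
E1,51.78,42.75,15.81
E2,30.97,22.37,-22.12
E3,72.14,-23.91,56.35
E4,71.56,16.08,65.03
E5,70,29.96,6.95
E6,35.88,37.82,10.32
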