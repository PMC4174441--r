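<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" width="1000" height="320" viewBox="0 0 1000 320">
<title>g1 coverage</title>
<rect x="0" y="0" width="1000" height="320" fill="white"/>
<polyline class="coverage-track" data-replicate="1" fill="none" stroke="red" stroke-width="1" points="45.00,240.00 49.56,240.00 51.08,127.50 58.67,127.50 60.19,15.00 110.33,15.00 111.84,127.50 117.92,127.50 119.44,15.00 134.63,15.00 136.15,127.50 165.02,127.50 166.54,15.00 178.69,15.00 180.21,127.50 195.40,127.50 196.92,240.00 360.99,240.00 362.51,127.50 482.53,127.50 484.05,240.00 803.08,240.00 804.60,127.50 833.46,127.50 834.98,15.00 879.04,15.00 880.56,127.50 909.42,127.50 910.94,240.00 955.00,240.00"/>
<polyline class="coverage-track" data-replicate="2" fill="none" stroke="green" stroke-width="1" points="45.00,240.00 49.56,240.00 51.08,127.50 58.67,127.50 60.19,15.00 110.33,15.00 111.84,127.50 117.92,127.50 119.44,15.00 134.63,15.00 136.15,127.50 165.02,127.50 166.54,15.00 178.69,15.00 180.21,127.50 195.40,127.50 196.92,240.00 360.99,240.00 362.51,127.50 482.53,127.50 484.05,240.00 803.08,240.00 804.60,127.50 833.46,127.50 834.98,15.00 879.04,15.00 880.56,127.50 909.42,127.50 910.94,240.00 955.00,240.00"/>
<polyline class="coverage-track" data-replicate="3" fill="none" stroke="blue" stroke-width="1" points="45.00,240.00 49.56,240.00 51.08,127.50 58.67,127.50 60.19,15.00 110.33,15.00 111.84,127.50 117.92,127.50 119.44,15.00 134.63,15.00 136.15,127.50 165.02,127.50 166.54,15.00 178.69,15.00 180.21,127.50 195.40,127.50 196.92,240.00 360.99,240.00 362.51,127.50 482.53,127.50 484.05,240.00 803.08,240.00 804.60,127.50 833.46,127.50 834.98,15.00 879.04,15.00 880.56,127.50 909.42,127.50 910.94,240.00 955.00,240.00"/>
<text x="40.00" y="19.00" font-size="11" text-anchor="end">2</text>
<text x="40.00" y="244.00" font-size="11" text-anchor="end">0</text>
<line class="intron" x1="45.00" y1="265.00" x2="955.00" y2="265.00" stroke="black" stroke-width="1"/>
<rect class="exon" x="45.00" y="258.00" width="150.40" height="14" fill="black" fill-opacity="1.000"/>
<rect class="exon" x="348.84" y="258.00" width="150.40" height="14" fill="black" fill-opacity="0.500"/>
<rect class="exon" x="804.60" y="258.00" width="150.40" height="14" fill="black" fill-opacity="1.000"/>
<text x="45.00" y="298.00" font-size="11" text-anchor="start">chr1:101</text>
<text x="955.00" y="298.00" font-size="11" text-anchor="end">700</text>
<text x="500.00" y="298.00" font-size="12" text-anchor="middle" font-style="italic">g1</text>
</svg>
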