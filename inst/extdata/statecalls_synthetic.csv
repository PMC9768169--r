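"id","rule","values","distance_nm","fold","state"
"snap01","snapshot","2.899",NA,NA,"OFF"
"snap02","snapshot","6.74",NA,NA,"ON"
"snap03","snapshot","0.418",NA,NA,"OFF"
"snap04","snapshot","0.425",NA,NA,"OFF"
"snap05","snapshot","0.316",NA,NA,"OFF"
"snap06","snapshot","0.63",NA,NA,"OFF"
"snap07","snapshot","0.945",NA,NA,"OFF"
"snap08","snapshot","5.909",NA,NA,"ON"
"snap09","snapshot","0.468",NA,NA,"OFF"
"snap10","snapshot","4.248",NA,NA,"ON"
"snap11","snapshot","4.192",NA,NA,"ON"
"snap12","snapshot","0.56",NA,NA,"OFF"
"snap13","snapshot","0.375",NA,NA,"OFF"
"snap14","snapshot","1.129",NA,NA,"OFF"
"snap15","snapshot","1.779",NA,NA,"OFF"
"snap16","snapshot","3.817",NA,NA,"ON"
"snap17","snapshot","0.44",NA,NA,"OFF"
"snap18","snapshot","3.402",NA,NA,"ON"
"snap19","snapshot","8.218",NA,NA,"ON"
"snap20","snapshot","3.22",NA,NA,"ON"
"snap21","snapshot","6.924",NA,NA,"ON"
"snap22","snapshot","0.646",NA,NA,"OFF"
"snap23","snapshot","0.63",NA,NA,"OFF"
"snap24","snapshot","2.309",NA,NA,"OFF"
"snap25","snapshot","0.943",NA,NA,"OFF"
"trace01","trace","0.654;0.475;1.319;5.174;0.86;1.766;4.645;0.721",NA,NA,"ON"
"trace02","trace","0.481;2.469;1.05;0.341;4.557;0.482;3.163;0.951",NA,NA,"OFF"
"trace03","trace","3.605;2.057;2.062;1.577;0.977;1.938;0.369;4.521",NA,NA,"OFF"
"trace04","trace","1.221;0.444;6.616;2.721;4.764;8.485;1.448;0.364",NA,NA,"ON"
"trace05","trace","0.699;2.862;2.477;0.624;3.754;0.667;3.413;5.326",NA,NA,"ON"
"trace06","trace","0.789;0.849;1.032;1.727;1.889;0.815;1.06;1.14",NA,NA,"OFF"
"trace07","trace","0.367;0.313;1.552;2.846;2.465;6.176;7.354;3.794",NA,NA,"ON"
"trace08","trace","2.278;1.832;0.336;3.833;8.216;0.453;8.545;5.344",NA,NA,"ON"
"trace09","trace","5.29;0.711;4.784;1.003;0.461;0.883;0.42;1.505",NA,NA,"ON"
"trace10","trace","1.177;1.462;5.938;0.416;0.78;1.309;0.361;2.044",NA,NA,"ON"
"trace11","trace","0.454;0.705;4.125;1.76;0.428;3.96;1.169;1.751",NA,NA,"OFF"
"trace12","trace","0.682;6.842;0.898;0.358;0.427;1.376;1.114;2.587",NA,NA,"ON"
"trace13","trace","2.619;3.516;2.992;5.624;1.248;0.827;5.781;8.049",NA,NA,"ON"
"trace14","trace","2.253;2.608;0.644;2.029;0.446;0.598;0.463;1.86",NA,NA,"OFF"
"trace15","trace","7.649;1.384;4.182;1.692;1.17;1.15;1.466;5.853",NA,NA,"ON"
"trace16","trace","1.625;5.054;0.451;1.136;8.348;0.346;4.045;0.332",NA,NA,"ON"
"trace17","trace","3.767;8.036;2.822;5.165;1.424;0.859;1.351;3.264",NA,NA,"ON"
"trace18","trace","2.103;0.442;0.998;1.009;0.946;0.686;2.607;0.301",NA,NA,"OFF"
"trace19","trace","0.909;5.853;1.7;6.679;2.05;6.876;0.871;5.242",NA,NA,"ON"
"trace20","trace","0.76;2.076;1.176;2.621;1.495;0.392;8.208;1.26",NA,NA,"ON"
"rf01","rf_proximity",NA,410.2,2.451,"OFF"
"rf02","rf_proximity",NA,145.9,4.878,"ON"
"rf03","rf_proximity",NA,318.4,3.004,"ON"
"rf04","rf_proximity",NA,652,0.997,"OFF"
"rf05","rf_proximity",NA,65.1,3.388,"ON"
"rf06","rf_proximity",NA,396.9,4.605,"OFF"
"rf07","rf_proximity",NA,385.5,1.479,"OFF"
"rf08","rf_proximity",NA,147.8,2.867,"ON"
"rf09","rf_proximity",NA,152.9,2.168,"ON"
"rf10","rf_proximity",NA,659,2.517,"OFF"
"rf11","rf_proximity",NA,344.1,2.403,"ON"
"rf12","rf_proximity",NA,500.3,3.907,"OFF"
"rf13","rf_proximity",NA,712.8,3.922,"OFF"
"rf14","rf_proximity",NA,377.3,1.847,"OFF"
"rf15","rf_proximity",NA,480.2,1.233,"OFF"
"rf16","rf_proximity",NA,520.8,1.544,"OFF"
"rf17","rf_proximity",NA,152,3.897,"ON"
"rf18","rf_proximity",NA,210.9,3.824,"ON"
"rf19","rf_proximity",NA,371,2.784,"ON"
"rf20","rf_proximity",NA,700.3,1.037,"OFF"
"rf21","rf_proximity",NA,643.9,1.329,"OFF"
"rf22","rf_proximity",NA,768.2,2.907,"OFF"
"rf23","rf_proximity",NA,587,2.223,"OFF"
"rf24","rf_proximity",NA,154.8,2.543,"ON"
"rf25","rf_proximity",NA,379.8,2.101,"ON"
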