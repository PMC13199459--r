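n_records: 768
exclusive_groups:
- name: hour
  categories:
  - Accident_0000_to_0600
  - Accident_0600_to_1200
  - Accident_1200_to_1800
  - Accident_1800_to_2400
  probs:
  - 0.0677083
  - 0.2734375
  - 0.3242188
  - 0.3346354
- name: weather
  categories:
  - Weather_Sunny
  - Weather_Rainy
  - Weather_Snowy
  - Weather_Cloudy
  probs:
  - 0.984375
  - 0.0026042
  - 0.0026042
  - 0.0104167
- name: accident_type
  categories:
  - Overturn_Occurred
  - One_Vehicle_Accident
  - Collision_with_Fixed_Object
  - Multiple_Vehicle_Accident
  - Pedestrian_Accident
  - Other_Accident_Type
  probs:
  - 0.140625
  - 0.6289062
  - 0.015625
  - 0.1158854
  - 0.0299479
  - 0.0690104
- name: collision_type
  categories:
  - Front_to_Back_Collision
  - Sliding_Out_of_Road
  - Front_to_Front_Collision
  - Front_to_Side_Collision
  - Upside_Down_Collision
  - Side_to_Side_Collision
  - Other_Collision_Type
  probs:
  - 0.3385417
  - 0.0729167
  - 0.2265625
  - 0.2304688
  - 0.0846354
  - 0.0286458
  - 0.0182292
- name: accident_cause
  categories:
  - Inattention_Cause
  - Loss_of_Control_Cause
  - Speeding_Cause
  - Left_Deviation_Cause
  - Priority_Violation_Cause
  - Unsafe_Distance_cause
  - Lane_Change_Cause
  - Alertness_Cause
  - Vehicle_Defect_Cause
  - Reversing_Cause
  - Wrong_Way_Cause
  - Overtaking_Cause
  - Prohibited_Turn_Cause
  - Other_Cause
  probs:
  - 0.4518229
  - 0.0885417
  - 0.0403646
  - 0.0768229
  - 0.1184896
  - 0.0364583
  - 0.0234375
  - 0.0039062
  - 0.0299479
  - 0.0234375
  - 0.0130208
  - 0.0065104
  - 0.0065104
  - 0.0807292
- name: second_vehicle
  categories:
  - Truck_Involved
  - Bus_Involved
  - Motorcycle_Involved
  - No_Second_Vehicle
  probs:
  - 0.390625
  - 0.0143229
  - 0.1015625
  - 0.4934896
- name: lighting
  categories:
  - Daylight
  - Dark
  - Dusk_Dawn
  probs:
  - 0.5585938
  - 0.1888021
  - 0.2526042
- name: pavement
  categories:
  - Pavement_Acceptable
  - Pavement_Low_Failure
  - Pavement_Moderate_Failure
  - Pavement_Severe_Failure
  probs:
  - 0.6367188
  - 0.3190104
  - 0.0364583
  - 0.0078125
independent_flags:
  Weekend: 0.2877604
  Holiday: 0.2122396
  FEV_at_Fault: 0.5
  Straight_Road: 0.5
  Single_Lane_Road: 0.5
dgp:
  fixed_coefs:
    constant: 0.07
    Unsafe_Distance_cause: -1.35
    Vehicle_Defect_Cause: 1.1
    Reversing_Cause: -3.16
    Overturn_Occurred: 1.25
    Collision_with_Fixed_Object: -1.87
    Accident_0000_to_0600: 1.12
    Truck_Involved: -2.2
    Motorcycle_Involved: 1.13
    Single_Lane_Road: 0.391
  random_var: Front_to_Back_Collision
  het_mean_coefs:
    constant: -0.99
    FEV_at_Fault: -0.74
    Straight_Road: 0.913
  random_sd: 1.0
  thresholds:
  - -1.07
  - 3.18
  noise_law: logistic
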